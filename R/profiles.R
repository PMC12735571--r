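# Built-in three-point dissolution profiles of the reference product and
# the optimized extended-release formulation (percent released at 1, 2.5
# and 13 h), and the Weibull release inputs fit to them.

#' Reference and optimized dissolution profiles
#'
#' Three-point cumulative dissolution profiles (pH 6.8, 100 rpm): the
#' reference product releases 23/58/77% at 1/2.5/13 h, the optimized
#' extended-release formulation 22/55/76%. These are the inputs of the f2
#' worked example and the virtual bioequivalence headline comparison.
#'
#' @return A tibble with `time_h` and `pct_released`.
#' @examples
#' f2_similarity(reference_profile(), optimized_profile())
#' @export
reference_profile <- function() {
  tibble::tibble(time_h = c(1, 2.5, 13), pct_released = c(23, 58, 77))
}

#' @rdname reference_profile
#' @export
optimized_profile <- function() {
  tibble::tibble(time_h = c(1, 2.5, 13), pct_released = c(22, 55, 76))
}

#' Weibull release inputs for the reference and optimized formulations
#'
#' Fits Weibull release kinetics to the printed three-point profiles.
#' With only three points the fitter's reduced single-phase
#' parameterization (`w1 = 1`) is used — the documented fallback for
#' under-determined double-phase fits.
#'
#' @return Named list with `reference` and `test` [release_input()]s (both
#'   `xr_weibull`), plus the underlying `weibull_fit` objects.
#' @export
donepezil_release_inputs <- function() {
  ref_fit <- fit_weibull_release(reference_profile())
  opt_fit <- fit_weibull_release(optimized_profile())
  list(
    reference = release_input("xr_weibull", weibull = ref_fit$params),
    test = release_input("xr_weibull", weibull = opt_fit$params),
    reference_fit = ref_fit,
    test_fit = opt_fit
  )
}
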