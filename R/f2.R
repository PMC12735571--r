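#' Dissolution profile similarity factor (f2)
#'
#' The similarity factor compares two cumulative dissolution profiles on
#' their shared sampling times:
#' \deqn{f_2 = 50 \log_{10}\left(100\left[1 + \frac{1}{n}\sum_t (R_t - T_t)^2
#'   \right]^{-1/2}\right)}
#' Identical profiles give \eqn{f_2 = 100}; a uniform 10-percentage-point
#' difference at every timepoint gives \eqn{f_2 \approx 50}, the conventional
#' similarity threshold (`similar` is `f2 > 50`).
#'
#' Following the standard regulatory convention, at most one timepoint after
#' both profiles exceed 85% released is retained (`cap_85 = TRUE`); this
#' prevents inflating similarity with points where both products are
#' essentially fully dissolved.
#'
#' @param reference,test Dissolution profiles: data frames with `time_h` and
#'   `pct_released` columns (a `vessel_id` column is averaged out first).
#' @param cap_85 Apply the at-most-one-point-above-85% rule? Default `TRUE`.
#' @param time_tol Absolute tolerance (h) when matching shared timepoints.
#'
#' @return A one-row tibble: `f2`, `n_points`, `similar`.
#' @examples
#' ref <- tibble::tibble(time_h = c(1, 2.5, 13), pct_released = c(23, 58, 77))
#' tst <- tibble::tibble(time_h = c(1, 2.5, 13), pct_released = c(22, 55, 76))
#' f2_similarity(ref, tst)
#' @export
f2_similarity <- function(reference, test, cap_85 = TRUE, time_tol = 1e-6) {
  ref <- mean_profile(as_profile(reference, arg = "reference"))
  tst <- mean_profile(as_profile(test, arg = "test"))
  idx <- match_times(ref$time_h, tst$time_h, time_tol)
  if (nrow(idx) < 3) {
    abort("f2 needs at least 3 shared timepoints.",
          class = "formsim_insufficient_data")
  }
  R <- ref$pct_released[idx$i]
  T_ <- tst$pct_released[idx$j]
  if (cap_85) {
    over <- which(R > 85 & T_ > 85)
    if (length(over) > 1) {
      keep <- seq_len(over[1])
      R <- R[keep]
      T_ <- T_[keep]
    }
  }
  n <- length(R)
  f2 <- 50 * log10(100 * (1 + mean((R - T_)^2))^(-0.5))
  tibble::tibble(f2 = f2, n_points = n, similar = f2 > 50)
}

mean_profile <- function(prof) {
  if (!"vessel_id" %in% names(prof)) return(prof)
  prof |>
    dplyr::group_by(.data$time_h) |>
    dplyr::summarise(pct_released = mean(.data$pct_released),
                     .groups = "drop")
}

match_times <- function(a, b, tol) {
  j <- vapply(a, function(t) {
    hit <- which(abs(b - t) <= tol)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  tibble::tibble(i = which(!is.na(j)), j = j[!is.na(j)])
}

#' Bootstrap f2 from per-vessel dissolution profiles
#'
#' Resamples dissolution vessels with replacement within each arm, computes
#' f2 on the resampled mean profiles, and reports a percentile confidence
#' interval. The conservative decision statistic is the lower (5th
#' percentile by default) bound: similarity is declared when it exceeds 50.
#'
#' @inheritParams f2_similarity
#' @param reference,test Data frames with `time_h`, `pct_released` and
#'   `vessel_id` columns; at least 2 vessels per arm.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed; results are bit-reproducible for a fixed seed.
#' @param probs Percentiles for the interval, default `c(0.05, 0.95)`.
#'
#' @return A one-row tibble: point-estimate `f2` (on the observed means),
#'   `n_points`, `ci_lower`, `ci_upper`, `similar` (lower bound > 50),
#'   `n_boot`.
#' @export
f2_bootstrap <- function(reference, test, n_boot = 2000, seed = 1,
                         probs = c(0.05, 0.95), cap_85 = TRUE,
                         time_tol = 1e-6) {
  ref <- as_profile(reference, arg = "reference")
  tst <- as_profile(test, arg = "test")
  for (nm in c("reference", "test")) {
    prof <- if (nm == "reference") ref else tst
    if (!"vessel_id" %in% names(prof) ||
        length(unique(prof$vessel_id)) < 2) {
      abort(sprintf("`%s` needs >= 2 vessels for the bootstrap.", nm),
            class = "formsim_insufficient_replicates")
    }
  }
  ref_v <- split(ref, ref$vessel_id)
  tst_v <- split(tst, tst$vessel_id)
  point <- f2_similarity(ref, tst, cap_85 = cap_85, time_tol = time_tol)
  relabel <- function(vs) {
    # fresh vessel ids so that resampling the same vessel twice keeps
    # per-vessel times strictly increasing
    dplyr::bind_rows(purrr::map2(vs, seq_along(vs), function(v, i) {
      v$vessel_id <- i
      v
    }))
  }
  stat <- function(rv, tv) {
    f2_similarity(relabel(rv), relabel(tv),
                  cap_85 = cap_85, time_tol = time_tol)$f2
  }
  draws <- with_seed(derive_seed(seed, "f2-bootstrap"), {
    vapply(seq_len(n_boot), function(b) {
      stat(ref_v[sample.int(length(ref_v), replace = TRUE)],
           tst_v[sample.int(length(tst_v), replace = TRUE)])
    }, numeric(1))
  })
  ci <- unname(quantile(draws, probs = probs, type = 7))
  tibble::tibble(
    f2 = point$f2, n_points = point$n_points,
    ci_lower = ci[1], ci_upper = ci[2],
    similar = ci[1] > 50, n_boot = n_boot
  )
}
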