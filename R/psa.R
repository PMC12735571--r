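# One-at-a-time parameter sensitivity analysis over the absorption model.

#' Parameters eligible for sensitivity analysis and variability
#'
#' The enumerated parameter set spans formulation performance (Weibull lag,
#' plateau, shapes, scales), permeability, gastric emptying and metabolic
#' capacity.
#'
#' @return Character vector of parameter names.
#' @export
psa_parameters <- function() {
  c("lag_time", "fmax", "weibshape1", "weibshape2", "weibscale1",
    "weibscale2", "peff", "vmax_cyp3a4", "vmax_cyp2d6",
    "stomach_transit_time")
}

# Apply a multiplicative perturbation to one named parameter of an
# absorption_config. Weibull-release parameters require XR mode.
modify_config <- function(config, parameter, multiplier) {
  stopifnot(inherits(config, "absorption_config"))
  if (!parameter %in% psa_parameters()) {
    abort(sprintf("Unknown parameter `%s`; see psa_parameters().", parameter),
          class = "formsim_invalid_parameter")
  }
  check_number(multiplier, "multiplier", 1e-9, Inf)
  wb_field <- c(lag_time = "lag", fmax = "fmax",
                weibshape1 = "shape1", weibshape2 = "shape2",
                weibscale1 = "scale1", weibscale2 = "scale2")
  if (parameter %in% names(wb_field)) {
    if (config$release$mode != "xr_weibull") {
      abort("Weibull parameters only apply to XR (Weibull) release inputs.",
            class = "formsim_invalid_parameter")
    }
    f <- wb_field[[parameter]]
    wb <- unclass(config$release$weibull)
    wb[[f]] <- wb[[f]] * multiplier
    if (f == "fmax") wb[[f]] <- min(wb[[f]], 110)
    config$release$weibull <- do.call(weibull_release, wb)
  } else if (parameter == "peff") {
    config$drug$peff_cm_s <- config$drug$peff_cm_s * multiplier
  } else if (parameter == "stomach_transit_time") {
    config$gi$transit_h[config$gi$segment == "stomach"] <-
      config$gi$transit_h[config$gi$segment == "stomach"] * multiplier
  } else if (parameter == "vmax_cyp3a4") {
    config$enzymes$cyp3a4$vmax <- config$enzymes$cyp3a4$vmax * multiplier
    config$enzymes$cyp3a4$vmax_mg_h <-
      config$enzymes$cyp3a4$vmax_mg_h * multiplier
  } else if (parameter == "vmax_cyp2d6") {
    config$enzymes$cyp2d6$vmax <- config$enzymes$cyp2d6$vmax * multiplier
    config$enzymes$cyp2d6$vmax_mg_h <-
      config$enzymes$cyp2d6$vmax_mg_h * multiplier
  }
  config
}

#' One-at-a-time parameter sensitivity analysis
#'
#' Re-simulates the absorption model over a multiplicative sweep of a
#' single parameter (default nine log-spaced multipliers from 0.25x to 4x,
#' which includes the exact baseline at 1x) and computes the normalized
#' sensitivity coefficient (elasticity) of each PK metric at baseline by a
#' central difference at +/-`rel_step`:
#' \eqn{d\log(metric) / d\log(parameter)}. Elasticities are unit-free, so
#' rankings are comparable across parameters.
#'
#' @param config Baseline [absorption_config()]; must simulate cleanly.
#' @param parameter One of [psa_parameters()].
#' @param sweep Multiplicative sweep grid (> 0); default
#'   `2^seq(-2, 2, length.out = 9)`.
#' @param rel_step Relative step for the central-difference elasticity,
#'   default 0.1.
#' @param duration_h,dt_h Passed to [simulate_absorption()].
#'
#' @return An object of class `psa_result`: `sweep` (tibble with
#'   `parameter`, `multiplier`, `value`, `cmax`, `tmax`, `auc_0_t`,
#'   `fa_total`; failed sweep points carry `NA` metrics), `sensitivity`
#'   (tibble `parameter`, `metric`, `elasticity`), and the baseline
#'   simulation.
#' @export
run_psa <- function(config, parameter, sweep = 2^seq(-2, 2, length.out = 9),
                    rel_step = 0.1, duration_h = 72, dt_h = 0.1) {
  stopifnot(all(sweep > 0))
  baseline <- simulate_absorption(config, duration_h, dt_h)
  base_value <- parameter_value(config, parameter)
  sim_at <- function(mult) {
    if (identical(mult, 1)) return(baseline)
    tryCatch(
      simulate_absorption(modify_config(config, parameter, mult),
                          duration_h, dt_h),
      error = function(e) NULL
    )
  }
  metrics_of <- function(sim) {
    if (is.null(sim)) {
      tibble::tibble(cmax = NA_real_, tmax = NA_real_, auc_0_t = NA_real_,
                     fa_total = NA_real_)
    } else {
      tibble::tibble(cmax = sim$pk$cmax, tmax = sim$pk$tmax,
                     auc_0_t = sim$pk$auc_0_t, fa_total = sim$fa_total)
    }
  }
  sweep_tbl <- dplyr::bind_cols(
    tibble::tibble(parameter = parameter, multiplier = sweep,
                   value = base_value * sweep),
    dplyr::bind_rows(lapply(sweep, function(m) metrics_of(sim_at(m))))
  )
  lo <- metrics_of(sim_at(1 - rel_step))
  hi <- metrics_of(sim_at(1 + rel_step))
  dlogx <- log(1 + rel_step) - log(1 - rel_step)
  elast <- function(metric) {
    a <- lo[[metric]]
    b <- hi[[metric]]
    if (is.na(a) || is.na(b) || a <= 0 || b <= 0) return(NA_real_)
    (log(b) - log(a)) / dlogx
  }
  sens <- tibble::tibble(
    parameter = parameter,
    metric = c("cmax", "tmax", "auc_0_t"),
    elasticity = unname(vapply(c("cmax", "tmax", "auc_0_t"), elast,
                               numeric(1)))
  )
  structure(list(sweep = sweep_tbl, sensitivity = sens,
                 baseline = baseline, parameter = parameter),
            class = "psa_result")
}

parameter_value <- function(config, parameter) {
  switch(parameter,
    peff = config$drug$peff_cm_s,
    stomach_transit_time =
      config$gi$transit_h[config$gi$segment == "stomach"],
    vmax_cyp3a4 = config$enzymes$cyp3a4$vmax,
    vmax_cyp2d6 = config$enzymes$cyp2d6$vmax,
    lag_time = config$release$weibull$lag,
    fmax = config$release$weibull$fmax,
    weibshape1 = config$release$weibull$shape1,
    weibshape2 = config$release$weibull$shape2,
    weibscale1 = config$release$weibull$scale1,
    weibscale2 = config$release$weibull$scale2
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %s over %d sweep points\n", x$parameter,
              nrow(x$sweep)))
  print(x$sensitivity)
  invisible(x)
}

#' @rdname run_psa
#' @param x,object A `psa_result`.
#' @param ... Unused.
#' @export
tidy.psa_result <- function(x, ...) x$sweep

#' @rdname run_psa
#' @export
autoplot.psa_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$sweep,
                              c("cmax", "tmax", "auc_0_t", "fa_total"),
                              names_to = "metric",
                              values_to = "metric_value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$multiplier,
                                     y = .data$metric_value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = sprintf("%s multiplier", object$parameter),
                  y = "Metric value") +
    ggplot2::theme_minimal()
}

#' Rank parameters by absolute normalized sensitivity
#'
#' Combines several [run_psa()] results into one table ordered by
#' decreasing absolute elasticity within each metric (ties broken
#' alphabetically by parameter name).
#'
#' @param results List of `psa_result` objects (>= 2 parameters).
#' @return Tibble: `metric`, `parameter`, `elasticity`,
#'   `abs_elasticity`, `rank`.
#' @export
rank_parameters <- function(results) {
  if (inherits(results, "psa_result")) results <- list(results)
  if (length(results) < 2) {
    abort("Ranking needs >= 2 analyzed parameters.",
          class = "formsim_insufficient_data")
  }
  dplyr::bind_rows(lapply(results, function(r) r$sensitivity)) |>
    dplyr::mutate(abs_elasticity = abs(.data$elasticity)) |>
    dplyr::arrange(.data$metric, dplyr::desc(.data$abs_elasticity),
                   .data$parameter) |>
    dplyr::group_by(.data$metric) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
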