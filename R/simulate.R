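# Compartmental gastrointestinal absorption + lumped disposition simulator.
#
# State layout (all amounts in mg), n = 9 GI segments:
#   y[1:9]    undissolved drug still inside the dosage form (transits)
#   y[10:18]  released solid particles per segment
#   y[19:27]  dissolved drug per segment
#   y[28]     central compartment amount
#   y[29]     peripheral compartment amount
#   y[30]     cumulative eliminated (first-pass + systemic)
#   y[31]     cumulative excreted from the ascending colon exit
#   y[32:40]  cumulative absorbed per segment (pre-first-pass)

N_SEG <- 9L

# Precompute everything the right-hand side needs from a configuration.
build_ode_pars <- function(config) {
  gi <- config$gi
  drug <- config$drug
  disp <- config$disposition
  kt <- 1 / gi$transit_h
  # absorption rate constant per segment, 1/h:
  # ka = 2 * Peff[cm/s] * scale / radius[cm] * 3600
  ka <- 2 * drug$peff_cm_s * gi$absorption_scale / gi$radius_cm * 3600
  csat <- approx(drug$solubility_ph, drug$solubility_mg_ml, xout = gi$ph,
                 rule = 2)$y # mg/mL, clamped outside the measured pH range
  vc_l <- disp$vc_l_kg * disp$body_weight_kg
  e3 <- config$enzymes$cyp3a4
  e2 <- config$enzymes$cyp2d6
  rel <- config$release
  list(
    kt = kt, ka = ka,
    sat_mg = csat * gi$volume_ml, # luminal capacity at saturation, mg
    kdiss = 50,                   # 1/h, fast dissolution of released solid
    vc_l = vc_l,
    k12 = disp$k12, k21 = disp$k21,
    q_h = disp$q_hepatic_l_h,
    fu = drug$fu_plasma, rbp = drug$blood_plasma_ratio,
    fub = drug$fu_plasma / drug$blood_plasma_ratio,
    mw = drug$molecular_weight,
    vmax1 = e3$sf * e3$vmax_mg_h, km1 = e3$km,
    vmax2 = e2$sf * e2$vmax_mg_h, km2 = e2$km,
    release_mode = rel$mode,
    weibull = rel$weibull,
    k_ir = rel$ir_rate_constant,
    dose = drug$dose_mg
  )
}

absorption_rhs <- function(t, y, p) {
  U <- y[1:9]; S <- y[10:18]; D <- y[19:27]
  Ac <- y[28]; Ap <- y[29]

  h <- if (p$release_mode == "xr_weibull") {
    weibull_release_hazard(p$weibull, t)
  } else {
    p$k_ir
  }
  rel <- h * U                                   # dosage form -> solid
  diss <- p$kdiss * S * pmax(0, 1 - D / p$sat_mg) # solid -> dissolved
  absflux <- p$ka * D                            # dissolved -> absorbed

  # transit of all three lumen species (segment i -> i+1; 9 -> excreted)
  tU <- p$kt * U; tS <- p$kt * S; tD <- p$kt * D

  dU <- -rel - tU; dU[2:9] <- dU[2:9] + tU[1:8]
  dS <- rel - diss - tS; dS[2:9] <- dS[2:9] + tS[1:8]
  dD <- diss - absflux - tD; dD[2:9] <- dD[2:9] + tD[1:8]

  # well-stirred liver: saturable intrinsic metabolism of unbound drug.
  # Extraction is evaluated at the liver *inlet* blood concentration
  # (systemic blood plus the absorbed gut flux diluted into hepatic blood
  # flow), so that both systemic elimination and first-pass extraction
  # saturate as concentrations approach Km.
  J <- sum(absflux)                      # absorbed flux entering the liver
  C <- Ac / p$vc_l                       # plasma conc, mg/L
  cb <- p$rbp * C                        # systemic blood conc
  cin_b <- cb + J / p$q_h                # liver inlet blood conc
  cu_um <- p$fub * cin_b * 1000 / p$mw   # unbound inlet conc, umol/L
  clint_u <- p$vmax1 / (p$km1 + cu_um) + p$vmax2 / (p$km2 + cu_um)
  clint_u <- clint_u * 1000 / p$mw       # (mg/h)/(mg/L) = L/h, unbound
  cl_b <- p$q_h * p$fub * clint_u / (p$q_h + p$fub * clint_u)
  eh <- cl_b / p$q_h                     # hepatic extraction ratio

  dAc <- (1 - eh) * J - eh * p$q_h * cb - p$k12 * Ac + p$k21 * Ap
  dAp <- p$k12 * Ac - p$k21 * Ap
  dElim <- eh * (J + p$q_h * cb)
  dExc <- tU[9] + tS[9] + tD[9]

  list(c(dU, dS, dD, dAc, dAp, dElim, dExc, absflux))
}

#' Simulate oral absorption and plasma pharmacokinetics
#'
#' Integrates the compartmental gastrointestinal transit/absorption model:
#' the dose travels as an intact dosage form releasing drug per the
#' configured schedule (Weibull for extended release, first-order for
#' immediate release) into nine sequential lumen segments; released solid
#' dissolves up to the pH-dependent luminal saturation; dissolved drug is
#' absorbed at `ka = 2*Peff*scale/radius` per segment, passes a
#' well-stirred liver with saturable CYP3A4 + CYP2D6 metabolism (first-pass
#' and systemic), and distributes over a two-compartment systemic model.
#'
#' @param config An [absorption_config()].
#' @param duration_h Simulation length, h (default 72; use >= 24 for
#'   extended-release inputs).
#' @param dt_h Output grid step, h (default 0.05).
#' @param rtol,atol Solver tolerances (deSolve::lsoda), defaults 1e-8 /
#'   1e-10.
#' @param balance_tol Maximum tolerated mass-balance error as a fraction of
#'   dose (default 1e-3); a violation raises a simulation-integrity error.
#'
#' @return An object of class `absorption_sim`: `profile` (tibble `time_h`,
#'   `conc_ng_ml`, segment totals and cumulative amounts), `fa_by_segment`
#'   (tibble), `fa_total` (percent), `pk` ([pk_metrics()] row),
#'   `mass_balance_error` (max relative error), and the `config`.
#' @examples
#' sim <- simulate_absorption(
#'   absorption_config(release = release_input("ir_first_order")),
#'   duration_h = 24, dt_h = 0.25)
#' sim$pk
#' @export
simulate_absorption <- function(config, duration_h = 72, dt_h = 0.05,
                                rtol = 1e-8, atol = 1e-10,
                                balance_tol = 1e-3) {
  stopifnot(inherits(config, "absorption_config"))
  check_number(duration_h, "duration_h", 1e-3, Inf)
  check_number(dt_h, "dt_h", 1e-6, duration_h)
  p <- build_ode_pars(config)
  y0 <- numeric(31 + N_SEG)
  y0[1] <- p$dose
  times <- seq(0, duration_h, by = dt_h)
  sol <- tryCatch(
    deSolve::lsoda(y0, times, absorption_rhs, p, rtol = rtol, atol = atol),
    warning = function(w) {
      abort(paste("ODE solver reported a problem:", conditionMessage(w)),
            class = "formsim_simulation_integrity")
    }
  )
  if (nrow(sol) < length(times)) {
    abort("ODE solver terminated early.",
          class = "formsim_simulation_integrity")
  }
  m <- unname(as.matrix(sol))
  total <- rowSums(m[, 2:32, drop = FALSE]) # all states except fa counters
  mb_err <- max(abs(total - p$dose)) / p$dose
  if (mb_err > balance_tol) {
    abort(sprintf("Mass balance violated: %.3g%% of dose.", 100 * mb_err),
          class = "formsim_simulation_integrity")
  }
  conc_ng_ml <- m[, 29] / p$vc_l * 1000 # mg/L == ug/mL -> ng/mL
  profile <- tibble::tibble(
    time_h = m[, 1],
    conc_ng_ml = conc_ng_ml,
    undissolved_mg = rowSums(m[, 2:10, drop = FALSE]),
    solid_mg = rowSums(m[, 11:19, drop = FALSE]),
    dissolved_mg = rowSums(m[, 20:28, drop = FALSE]),
    central_mg = m[, 29], peripheral_mg = m[, 30],
    eliminated_mg = m[, 31], excreted_mg = m[, 32],
    absorbed_mg = rowSums(m[, 33:41, drop = FALSE])
  )
  fa_seg <- 100 * m[nrow(m), 33:41] / p$dose
  fa_by_segment <- tibble::tibble(segment = config$gi$segment,
                                  fa_pct = fa_seg)
  pk <- pk_metrics(profile$time_h, profile$conc_ng_ml)
  structure(
    list(profile = profile, fa_by_segment = fa_by_segment,
         fa_total = sum(fa_seg), pk = pk,
         mass_balance_error = mb_err, config = config,
         duration_h = duration_h, dt_h = dt_h),
    class = "absorption_sim"
  )
}

#' @export
print.absorption_sim <- function(x, ...) {
  cat(sprintf(
    "<absorption_sim> %s, %.0f h\n  fa_total %.1f%%  Cmax %.2f ng/mL  Tmax %.2f h  AUC0-t %.1f ng*h/mL\n",
    x$config$release$mode, x$duration_h, x$fa_total,
    x$pk$cmax, x$pk$tmax, x$pk$auc_0_t))
  invisible(x)
}

#' @rdname simulate_absorption
#' @param x,object An `absorption_sim`.
#' @param ... Unused.
#' @export
glance.absorption_sim <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(mode = x$config$release$mode,
                   fa_total = x$fa_total,
                   mass_balance_error = x$mass_balance_error),
    x$pk
  )
}

#' @rdname simulate_absorption
#' @export
autoplot.absorption_sim <- function(object, ...) {
  ggplot2::ggplot(object$profile,
                  ggplot2::aes(x = .data$time_h, y = .data$conc_ng_ml)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Time (h)", y = "Plasma concentration (ng/mL)",
                  title = sprintf("%s: fa %.1f%%",
                                  object$config$release$mode,
                                  object$fa_total)) +
    ggplot2::theme_minimal()
}

#' Non-compartmental PK metrics from a concentration-time curve
#'
#' Cmax/Tmax are read from the sampling grid; AUC0-t uses the linear
#' trapezoid; AUC0-inf adds `Clast/lambda_z`, with the terminal slope
#' `lambda_z` from a log-linear fit over the last `n_tail` positive
#' concentrations. A non-negative terminal slope leaves `auc_inf` missing
#' with a warning.
#'
#' @param times Hours, strictly increasing, >= 3 points.
#' @param conc Concentrations (any consistent unit).
#' @param n_tail Points in the terminal log-linear fit (>= 3, default 3).
#' @return One-row tibble: `cmax`, `tmax`, `auc_0_t`, `auc_inf`,
#'   `lambda_z`.
#' @examples
#' pk_metrics(c(0, 1, 2), c(0, 10, 5))
#' @export
pk_metrics <- function(times, conc, n_tail = 3) {
  stopifnot(length(times) == length(conc))
  if (length(times) < 3) {
    abort("Need >= 3 points for PK metrics.",
          class = "formsim_insufficient_data")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort("`times` must be strictly increasing.",
          class = "formsim_invalid_parameter")
  }
  imax <- which.max(conc)
  cmax <- conc[imax]
  tmax <- times[imax]
  n <- length(times)
  auc <- sum(diff(times) * (conc[-1] + conc[-n]) / 2)
  lambda_z <- NA_real_
  auc_inf <- NA_real_
  pos <- which(conc > 0 & seq_along(conc) >= imax)
  if (cmax <= 0) {
    auc_inf <- auc # identically-zero curve
  } else if (length(pos) >= n_tail) {
    idx <- tail(pos, n_tail)
    fit <- lm(log(conc[idx]) ~ times[idx])
    slope <- coef(fit)[[2]]
    if (is.finite(slope) && slope < 0) {
      lambda_z <- -slope
      auc_inf <- auc + conc[n] / lambda_z
    } else {
      warn("Non-negative terminal slope; `auc_inf` reported as missing.")
    }
  } else {
    warn("Too few positive terminal points; `auc_inf` reported as missing.")
  }
  tibble::tibble(cmax = cmax, tmax = tmax, auc_0_t = auc,
                 auc_inf = auc_inf, lambda_z = lambda_z)
}

#' Average fold error of predicted vs observed PK metrics
#'
#' Geometric-mean bias across studies:
#' \eqn{AFE = 10^{\frac{1}{n}\sum_i \log_{10}(pred_i/obs_i)}}. AFE = 1
#' means no bias; predictions are conventionally satisfactory when AFE lies
#' in \[0.8, 1.25\].
#'
#' @param data Validation table: tibble with columns `study_id`, `metric`,
#'   `predicted`, `observed` (long format, one row per study x metric).
#' @param metric Metric(s) to evaluate, default all present.
#' @return Tibble with one row per metric: `metric`, `afe`, `n`, `pass`.
#' @examples
#' v <- tibble::tibble(study_id = 1:2, metric = "cmax",
#'                     predicted = c(20, 5), observed = c(10, 10))
#' afe(v) # ratios 2 and 0.5 cancel: AFE = 1
#' @export
afe <- function(data, metric = NULL) {
  stopifnot(is.data.frame(data),
            all(c("metric", "predicted", "observed") %in% names(data)))
  if (!is.null(metric)) data <- data[data$metric %in% metric, ]
  if (!nrow(data)) {
    abort("No rows for the requested metric(s).",
          class = "formsim_insufficient_data")
  }
  if (any(!is.finite(data$observed)) || any(data$observed <= 0) ||
      any(!is.finite(data$predicted)) || any(data$predicted <= 0)) {
    abort("Predicted and observed values must be positive and finite.",
          class = "formsim_invalid_observation")
  }
  data |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      afe = 10^mean(log10(.data$predicted / .data$observed)),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(pass = .data$afe >= 0.8 & .data$afe <= 1.25)
}
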