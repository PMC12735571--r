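# Virtual bioequivalence: populations, 2x2 crossover trials, BE statistics.

#' Parameter variability specification for virtual populations
#'
#' Between-subject (BSV) and within-subject (WSV) coefficients of
#' variation, percent, for the mechanistically varied parameters. Defaults
#' reproduce the tuned variability set used for the donepezil
#' extended-release assessment: CYP3A4/CYP2D6 Vmax 15/15, stomach transit
#' time 35/35, Peff 30/30, Weibull scales and shapes 5/5, Fmax 3.2/3.2
#' (the Weibull rows are in vitro dissolution variability applied to the
#' administered formulation; the rest are physiological). Multipliers are
#' log-normal with median 1.
#'
#' @param params Optional data frame with columns `parameter`, `bsv_cv`,
#'   `wsv_cv` to override the defaults.
#' @return A tibble of class `variability_spec`.
#' @export
variability_spec <- function(params = NULL) {
  out <- tibble::tibble(
    parameter = c("cyp3a4_vmax", "cyp2d6_vmax", "stomach_transit_time",
                  "peff", "weibscale1", "weibscale2", "weibshape1",
                  "weibshape2", "fmax"),
    bsv_cv = c(15, 15, 35, 30, 5, 5, 5, 5, 3.2),
    wsv_cv = c(15, 15, 35, 30, 5, 5, 5, 5, 3.2)
  )
  if (!is.null(params)) {
    stopifnot(all(c("parameter", "bsv_cv", "wsv_cv") %in% names(params)))
    for (i in seq_len(nrow(params))) {
      j <- match(params$parameter[i], out$parameter)
      if (is.na(j)) {
        abort(sprintf("Unknown variability parameter `%s`.",
                      params$parameter[i]),
              class = "formsim_invalid_parameter")
      }
      out$bsv_cv[j] <- params$bsv_cv[i]
      out$wsv_cv[j] <- params$wsv_cv[i]
    }
  }
  if (any(out$bsv_cv < 0) || any(out$wsv_cv < 0)) {
    abort("CVs must be >= 0.", class = "formsim_invalid_parameter")
  }
  class(out) <- c("variability_spec", class(out))
  out
}

# CV percent -> sdlog of a median-1 log-normal.
cv_to_sdlog <- function(cv_pct) sqrt(log(1 + (cv_pct / 100)^2))

#' Build a virtual crossover population
#'
#' Draws log-normal (median 1) parameter multipliers: one between-subject
#' (BSV) multiplier per subject and parameter, fixed across periods, and
#' independent within-subject (WSV) multipliers per period. The effective
#' multiplier in period p is `bsv * wsv_p`. With all CVs zero every
#' multiplier is exactly 1.
#'
#' @param spec A [variability_spec()].
#' @param n Number of subjects (>= 2).
#' @param seed RNG seed; the population is reproducible.
#' @param n_periods Number of periods, default 2.
#' @return Tibble of class `virtual_population`: one row per subject x
#'   parameter with columns `subject`, `parameter`, `bsv`, `wsv_p1`,
#'   `wsv_p2`, ...
#' @export
build_population <- function(spec = variability_spec(), n, seed = 1,
                             n_periods = 2) {
  stopifnot(inherits(spec, "variability_spec"))
  check_number(n, "n", 2, Inf)
  n <- as.integer(n)
  out <- with_seed(derive_seed(seed, "population"), {
    grid <- tidyr::expand_grid(subject = seq_len(n),
                               parameter = spec$parameter)
    grid <- dplyr::left_join(grid, spec, by = "parameter")
    grid$bsv <- exp(rnorm(nrow(grid), 0, cv_to_sdlog(grid$bsv_cv)))
    for (p in seq_len(n_periods)) {
      grid[[paste0("wsv_p", p)]] <-
        exp(rnorm(nrow(grid), 0, cv_to_sdlog(grid$wsv_cv)))
    }
    grid
  })
  out <- dplyr::select(out, -"bsv_cv", -"wsv_cv")
  class(out) <- c("virtual_population", class(out))
  out
}

# Map variability parameter names onto modify_config() names.
vbe_param_map <- c(
  cyp3a4_vmax = "vmax_cyp3a4", cyp2d6_vmax = "vmax_cyp2d6",
  stomach_transit_time = "stomach_transit_time", peff = "peff",
  weibscale1 = "weibscale1", weibscale2 = "weibscale2",
  weibshape1 = "weibshape1", weibshape2 = "weibshape2", fmax = "fmax"
)

# Simulate one subject-period: apply multipliers, return PK metrics.
simulate_period <- function(config, release, multipliers, duration_h, dt_h) {
  config$release <- release
  for (i in seq_len(nrow(multipliers))) {
    par <- vbe_param_map[[multipliers$parameter[i]]]
    m <- multipliers$mult[i]
    if (m == 1) next
    is_formulation <- startsWith(par, "weib") || par %in%
      c("fmax", "lag_time")
    if (is_formulation && config$release$mode != "xr_weibull") next
    config <- modify_config(config, par, m)
  }
  sim <- simulate_absorption(config, duration_h, dt_h)
  tibble::tibble(cmax = sim$pk$cmax, auc_0_t = sim$pk$auc_0_t)
}

#' Two-one-sided-tests analysis of a 2x2 crossover
#'
#' Log-scale linear model of a two-sequence, two-period crossover
#' (treatment + period + subject fixed effects); the geometric mean ratio
#' is `exp` of the treatment effect and the 90% confidence interval uses
#' the within-subject residual variance on `n - 2` degrees of freedom —
#' the classical TOST/90%-CI bioequivalence analysis. With zero residual
#' variance the interval degenerates to the point estimate.
#'
#' @param data Tibble with columns `subject`, `sequence` (`"TR"`/`"RT"`),
#'   `period` (1/2), `treatment` (`"T"`/`"R"`), and the positive metric
#'   `value`.
#' @param alpha One-sided test level, default 0.05 (90% CI).
#' @param limits BE acceptance limits for the GMR, default `c(0.8, 1.25)`.
#' @return One-row tibble: `gmr`, `ci_lower`, `ci_upper`, `pass`,
#'   `cv_within_pct` (residual within-subject CV), `df`.
#' @export
be_analysis <- function(data, alpha = 0.05, limits = c(0.8, 1.25)) {
  need <- c("subject", "sequence", "period", "treatment", "value")
  stopifnot(is.data.frame(data), all(need %in% names(data)))
  if (any(data$value <= 0)) {
    abort("Metric values must be positive for log-scale analysis.",
          class = "formsim_invalid_parameter")
  }
  d <- data.frame(
    y = log(data$value),
    treatment = factor(data$treatment, levels = c("R", "T")),
    period = factor(data$period),
    subject = factor(data$subject)
  )
  fit <- lm(y ~ treatment + period + subject, data = d)
  est <- coef(fit)[["treatmentT"]]
  df <- fit$df.residual
  mse <- sum(fit$residuals^2) / max(df, 1)
  # For the balanced 2x2 this reduces to sqrt(mse * 2 / n); the model
  # covariance stays correct under mild imbalance.
  se <- sqrt(suppressWarnings(stats::vcov(fit))["treatmentT", "treatmentT"])
  tcrit <- if (df > 0) qt(1 - alpha, df) else 0
  ci <- exp(est + c(-1, 1) * tcrit * se)
  gmr <- exp(est)
  tibble::tibble(
    gmr = gmr, ci_lower = ci[1], ci_upper = ci[2],
    pass = ci[1] >= limits[1] & ci[2] <= limits[2],
    cv_within_pct = 100 * sqrt(exp(mse) - 1),
    df = df
  )
}

#' Run one virtual 2x2 crossover bioequivalence trial
#'
#' Assigns a balanced TR/RT sequence split over the population, simulates
#' every subject-period through the absorption model with that subject's
#' BSV and period WSV multipliers applied (mechanistic within-subject
#' variability: physiology and formulation parameters are re-drawn per
#' period, not noise added to the PK metrics), and analyses Cmax and
#' AUC0-t on the log scale.
#'
#' @param test,reference [release_input()]s for the test and reference
#'   formulations.
#' @param population A [build_population()] tibble (even number of
#'   subjects).
#' @param config Base [absorption_config()]; its `release` slot is
#'   replaced per period.
#' @param duration_h,dt_h Simulation window and grid, defaults 72 h /
#'   0.1 h.
#' @param alpha,limits Passed to [be_analysis()].
#' @return Object of class `vbe_trial`: `observations` (subject x period
#'   metric table) and `be` (per-metric [be_analysis()] rows plus
#'   `metric`), `pass` (all metrics pass).
#' @export
run_trial <- function(test, reference, population, config,
                      duration_h = 72, dt_h = 0.1,
                      alpha = 0.05, limits = c(0.8, 1.25)) {
  stopifnot(inherits(test, "release_input"),
            inherits(reference, "release_input"),
            inherits(population, "virtual_population"))
  subjects <- sort(unique(population$subject))
  n <- length(subjects)
  if (n %% 2 != 0) {
    abort("Population size must be even for balanced TR/RT sequences.",
          class = "formsim_invalid_parameter")
  }
  sequence <- rep(c("TR", "RT"), each = n / 2)
  obs <- vector("list", 2L * n)
  k <- 0L
  for (i in seq_len(n)) {
    subj_rows <- population[population$subject == subjects[i], ]
    for (period in 1:2) {
      trt <- substr(sequence[i], period, period)
      release <- if (trt == "T") test else reference
      mult <- tibble::tibble(
        parameter = subj_rows$parameter,
        mult = subj_rows$bsv * subj_rows[[paste0("wsv_p", period)]]
      )
      pk <- tryCatch(
        simulate_period(config, release, mult, duration_h, dt_h),
        error = function(e) {
          abort(sprintf("Subject %s period %d simulation failed: %s",
                        subjects[i], period, conditionMessage(e)),
                class = "formsim_trial_invalid")
        }
      )
      k <- k + 1L
      obs[[k]] <- dplyr::bind_cols(
        tibble::tibble(subject = subjects[i], sequence = sequence[i],
                       period = period, treatment = trt),
        pk
      )
    }
  }
  observations <- dplyr::bind_rows(obs)
  be <- dplyr::bind_rows(lapply(c("cmax", "auc_0_t"), function(metric) {
    dat <- observations
    dat$value <- dat[[metric]]
    dplyr::bind_cols(tibble::tibble(metric = metric),
                     be_analysis(dat, alpha = alpha, limits = limits))
  }))
  structure(list(observations = observations, be = be,
                 pass = all(be$pass), n_subjects = n),
            class = "vbe_trial")
}

#' @export
print.vbe_trial <- function(x, ...) {
  cat(sprintf("<vbe_trial> n = %d, %s\n", x$n_subjects,
              if (x$pass) "PASS" else "FAIL"))
  print(x$be)
  invisible(x)
}

#' Risk tier from passing-trial counts
#'
#' For 15 trials: low risk when >= 13 pass, moderate for 9-12, high below
#' 9; other trial counts use the same proportional cut-offs (13/15 and
#' 9/15).
#'
#' @param n_pass,n_trials Counts.
#' @return `"low"`, `"moderate"` or `"high"`.
#' @export
risk_tier <- function(n_pass, n_trials) {
  frac <- n_pass / n_trials
  if (frac >= 13 / 15) "low" else if (frac >= 9 / 15) "moderate" else "high"
}

#' Run a virtual bioequivalence study
#'
#' Simulates `n_trials` independent 2x2 crossover trials, each with a
#' freshly drawn virtual population (seed-derived streams), and aggregates
#' pass counts into a risk tier.
#'
#' @inheritParams run_trial
#' @param spec [variability_spec()].
#' @param n_subjects Subjects per trial (even), default 24.
#' @param n_trials Number of trials, default 15.
#' @param seed Base seed; trial populations derive from it.
#' @return Object of class `vbe_study`: `trials` (per trial x metric BE
#'   rows), `trial_pass` (logical), `n_pass`, `tier`.
#' @export
run_vbe_study <- function(test, reference, spec = variability_spec(),
                          config = absorption_config(release = reference),
                          n_subjects = 24, n_trials = 15, seed = 1,
                          duration_h = 72, dt_h = 0.1,
                          alpha = 0.05, limits = c(0.8, 1.25)) {
  check_number(n_trials, "n_trials", 1, Inf)
  trials <- lapply(seq_len(n_trials), function(tr) {
    pop <- build_population(spec, n_subjects,
                            seed = derive_seed(seed, paste0("trial-", tr)))
    run_trial(test, reference, pop, config, duration_h, dt_h,
              alpha, limits)
  })
  be <- dplyr::bind_rows(lapply(seq_along(trials), function(i) {
    dplyr::bind_cols(tibble::tibble(trial = i), trials[[i]]$be)
  }))
  trial_pass <- vapply(trials, function(t) t$pass, logical(1))
  structure(
    list(trials = be, trial_pass = trial_pass,
         n_pass = sum(trial_pass), n_trials = n_trials,
         n_subjects = n_subjects,
         tier = risk_tier(sum(trial_pass), n_trials), seed = seed),
    class = "vbe_study"
  )
}

#' @export
print.vbe_study <- function(x, ...) {
  cat(sprintf("<vbe_study> %d/%d trials pass (n = %d/trial) -> %s risk\n",
              x$n_pass, x$n_trials, x$n_subjects, x$tier))
  invisible(x)
}

#' @rdname run_vbe_study
#' @param x,object A `vbe_study`.
#' @param ... Unused.
#' @export
tidy.vbe_study <- function(x, ...) x$trials

#' @rdname run_vbe_study
#' @export
glance.vbe_study <- function(x, ...) {
  tibble::tibble(n_trials = x$n_trials, n_subjects = x$n_subjects,
                 n_pass = x$n_pass, tier = x$tier)
}

#' @rdname run_vbe_study
#' @export
autoplot.vbe_study <- function(object, ...) {
  ggplot2::ggplot(object$trials,
                  ggplot2::aes(x = factor(.data$trial), y = .data$gmr)) +
    ggplot2::geom_hline(yintercept = c(0.8, 1.25), linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 1, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lower,
                                          ymax = .data$ci_upper,
                                          colour = .data$pass)) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "Trial", y = "GMR (90% CI)") +
    ggplot2::theme_minimal()
}

#' Stepwise sample-size determination by empirical power
#'
#' Steps the per-trial population size upward until the fraction of
#' passing trials (empirical power) reaches the target, reusing the same
#' seed streams at every size (common random numbers) so the power curve
#' is monotone up to Monte-Carlo noise.
#'
#' @inheritParams run_vbe_study
#' @param start_n Starting population size (even, >= 6), default 12.
#' @param step Increment, default 6.
#' @param max_n Largest size tried, default 36.
#' @param power_target Required fraction of passing trials, default 0.8.
#' @return List of class `vbe_power`: `n_required` (smallest passing n, or
#'   `NA` if the target is unreachable by `max_n`) and `curve` (tibble
#'   `n`, `n_pass`, `power`).
#' @export
sample_size_step <- function(test, reference, spec = variability_spec(),
                             config = absorption_config(release = reference),
                             start_n = 12, step = 6, max_n = 36,
                             power_target = 0.8, n_trials = 15, seed = 1,
                             duration_h = 72, dt_h = 0.1) {
  check_number(start_n, "start_n", 6, Inf)
  if (start_n %% 2 != 0) {
    abort("`start_n` must be even.", class = "formsim_invalid_parameter")
  }
  sizes <- seq(start_n, max_n, by = step)
  curve <- list()
  n_required <- NA_integer_
  for (n in sizes) {
    study <- run_vbe_study(test, reference, spec, config,
                           n_subjects = n, n_trials = n_trials, seed = seed,
                           duration_h = duration_h, dt_h = dt_h)
    curve[[length(curve) + 1]] <- tibble::tibble(
      n = n, n_pass = study$n_pass, power = study$n_pass / n_trials)
    if (study$n_pass / n_trials >= power_target) {
      n_required <- n
      break
    }
  }
  structure(list(n_required = n_required,
                 curve = dplyr::bind_rows(curve),
                 power_target = power_target),
            class = "vbe_power")
}

#' @export
print.vbe_power <- function(x, ...) {
  cat(sprintf("<vbe_power> target %.0f%%: n = %s\n", 100 * x$power_target,
              if (is.na(x$n_required)) "not reached" else x$n_required))
  print(x$curve)
  invisible(x)
}
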