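# Synthetic data generators: design/response tables from known quadratic
# surfaces, multi-vessel dissolution profiles from Weibull truth curves,
# and pseudo-observed clinical PK datasets for exercising AFE validation.
# All outputs are pure functions of (spec, seed).

#' Synthetic Box-Behnken response dataset
#'
#' Generates a 17-run Box-Behnken design and responses Y1-Y4 drawn from
#' known generating quadratic surfaces plus Gaussian noise. The default
#' truth is the published retained-coefficient set
#' ([donepezil_release_surfaces()]), so the central-point Y1 response is
#' ~22% released at 1 h up to noise. The generating truth is attached for
#' recovery tests.
#'
#' @param truth Named list of `release_surface` objects (one per
#'   response), default [donepezil_release_surfaces()].
#' @param factors Factor specification, default [release_factors()].
#' @param n_center Center replicates, default 5.
#' @param sigma Response noise SD (percentage points), default 1; 0 gives
#'   exact surface values.
#' @param seed RNG seed.
#' @param out_dir Optional directory; when given, writes `bbd_design.csv`
#'   and `bbd_responses.csv`.
#' @return The design tibble with response columns appended; attributes
#'   `"truth"` (the generating surfaces) and `"sigma"`.
#' @export
make_bbd_dataset <- function(truth = donepezil_release_surfaces(),
                             factors = release_factors(), n_center = 5,
                             sigma = 1, seed = 1, out_dir = NULL) {
  check_number(sigma, "sigma", 0, Inf)
  design <- bbd_design(factors, n_center = n_center)
  fnames <- factors$name
  out <- with_seed(derive_seed(seed, "bbd"), {
    for (resp in names(truth)) {
      mu <- vapply(seq_len(nrow(design)), function(i) {
        eval_quadratic(as.list(truth[[resp]]$coefficients),
                       as.list(design[i, fnames]), fnames)
      }, numeric(1))
      design[[resp]] <- mu + rnorm(nrow(design), 0, sigma)
    }
    design
  })
  attr(out, "truth") <- truth
  attr(out, "sigma") <- sigma
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      as.data.frame(out)[c("run_id", fnames)],
      file.path(out_dir, "bbd_design.csv"), row.names = FALSE)
    utils::write.csv(
      as.data.frame(out)[c("run_id", names(truth))],
      file.path(out_dir, "bbd_responses.csv"), row.names = FALSE)
  }
  out
}

#' Synthetic multi-vessel dissolution dataset
#'
#' Samples each formulation's Weibull truth curve at the dissolution
#' schedule (0.5, 1, 2.5, 5, 13 h by default) for `n_vessels` vessels,
#' adds truncated Gaussian measurement noise, clips to \[0, 100\] and
#' enforces per-vessel monotonicity (cumulative release cannot decrease).
#'
#' @param truth Named list of [weibull_release()] truth curves, one per
#'   formulation.
#' @param times Sampling schedule (h).
#' @param n_vessels Vessels per formulation (>= 1), default 12.
#' @param sigma Measurement noise SD (percentage points), default 1.
#' @param seed RNG seed.
#' @param out_dir Optional directory; writes one
#'   `dissolution_<formulation>.csv` per truth curve.
#' @return Tibble: `formulation`, `vessel_id`, `time_h`, `pct_released`;
#'   attribute `"truth"`.
#' @export
make_dissolution_dataset <- function(truth,
                                     times = c(0.5, 1, 2.5, 5, 13),
                                     n_vessels = 12, sigma = 1, seed = 1,
                                     out_dir = NULL) {
  stopifnot(is.list(truth), length(truth) >= 1, !is.null(names(truth)))
  check_number(n_vessels, "n_vessels", 1, Inf)
  check_number(sigma, "sigma", 0, Inf)
  out <- with_seed(derive_seed(seed, "dissolution"), {
    dplyr::bind_rows(lapply(names(truth), function(form) {
      mu <- eval_weibull_release(truth[[form]], times)
      dplyr::bind_rows(lapply(seq_len(n_vessels), function(v) {
        y <- mu + rnorm(length(times), 0, sigma)
        y <- pmin(pmax(y, 0), 100)
        y <- cummax(y) # cumulative release is non-decreasing per vessel
        tibble::tibble(formulation = form, vessel_id = v,
                       time_h = times, pct_released = y)
      }))
    }))
  })
  attr(out, "truth") <- truth
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (form in names(truth)) {
      utils::write.csv(
        as.data.frame(out[out$formulation == form,
                          c("time_h", "pct_released", "vessel_id")]),
        file.path(out_dir, paste0("dissolution_", form, ".csv")),
        row.names = FALSE)
    }
  }
  out
}

#' Synthetic clinical validation dataset for AFE testing
#'
#' Emulates a multi-study validation set: for each pseudo-study the
#' baseline configuration is perturbed (multiplicative factors on
#' permeability, metabolic capacity and gastric emptying), the perturbed
#' model is simulated to produce the "observed" Cmax and AUC0-t, and the
#' unperturbed baseline prediction is paired with it. Zero perturbation
#' therefore gives AFE exactly 1.
#'
#' @param config Baseline [absorption_config()].
#' @param n_studies Number of pseudo-studies, default 9.
#' @param perturbation Half-width of the uniform multiplicative
#'   perturbation (e.g. 0.1 draws factors in \[0.9, 1.1\]), default 0.1.
#' @param seed RNG seed.
#' @param duration_h,dt_h Simulation settings.
#' @return Long validation tibble for [afe()]: `study_id`, `metric`,
#'   `predicted`, `observed`.
#' @export
make_clinical_dataset <- function(config, n_studies = 9,
                                  perturbation = 0.1, seed = 1,
                                  duration_h = 72, dt_h = 0.1) {
  check_number(n_studies, "n_studies", 1, Inf)
  check_number(perturbation, "perturbation", 0, 0.99)
  baseline <- simulate_absorption(config, duration_h, dt_h)
  pred <- tibble::tibble(metric = c("cmax", "auc_0_t"),
                         predicted = c(baseline$pk$cmax,
                                       baseline$pk$auc_0_t))
  pars <- c("peff", "vmax_cyp3a4", "vmax_cyp2d6", "stomach_transit_time")
  factors <- with_seed(derive_seed(seed, "clinical"), {
    matrix(runif(n_studies * length(pars), 1 - perturbation,
                 1 + perturbation),
           nrow = n_studies, dimnames = list(NULL, pars))
  })
  dplyr::bind_rows(lapply(seq_len(n_studies), function(s) {
    cfg <- config
    for (p in pars) cfg <- modify_config(cfg, p, factors[s, p])
    sim <- simulate_absorption(cfg, duration_h, dt_h)
    tibble::tibble(
      study_id = s,
      metric = c("cmax", "auc_0_t"),
      predicted = pred$predicted,
      observed = c(sim$pk$cmax, sim$pk$auc_0_t)
    )
  }))
}
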