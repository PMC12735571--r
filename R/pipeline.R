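#' Run the integrated formulation-development pipeline
#'
#' Executes the full workflow end to end: (1) generate a synthetic
#' Box-Behnken response dataset from the published truth surfaces and
#' refit the quadratic models; (2) optimize the composition against the
#' reference release targets; (3) fit Weibull release kinetics to the
#' reference and optimized dissolution profiles and compare them by f2;
#' (4) simulate extended- and immediate-release pharmacokinetics; (5)
#' build a pseudo-observed clinical dataset and validate by average fold
#' error; (6) rank parameter sensitivities; (7) run the virtual
#' bioequivalence study and categorize its risk. Reruns with the same
#' seed reproduce every output.
#'
#' @param seed Global seed; every stochastic stage derives its own stream.
#' @param out_dir Optional directory; when given, a machine-readable
#'   `pipeline_report.json` and intermediate CSVs are written there.
#' @param n_subjects,n_trials Virtual bioequivalence study size, defaults
#'   24 subjects and 15 trials.
#' @param psa_params Parameters to rank, default
#'   `c("peff", "weibscale1", "lag_time")`.
#' @param duration_h,dt_h Simulation window/grid for the PK stages.
#' @param bbd_sigma Noise SD for the synthetic design responses.
#' @return A list of class `formsim_pipeline` with one element per stage
#'   (`doe`, `optimization`, `dissolution`, `pk`, `validation`, `psa`,
#'   `vbe`) plus `summary`, a one-row tibble of the headline numbers.
#' @export
run_pipeline <- function(seed = 1, out_dir = NULL,
                         n_subjects = 24, n_trials = 15,
                         psa_params = c("peff", "weibscale1", "lag_time"),
                         duration_h = 72, dt_h = 0.1, bbd_sigma = 1) {
  # 1. DoE: synthetic responses from the published truth, refit
  bbd <- make_bbd_dataset(sigma = bbd_sigma,
                          seed = derive_seed(seed, "pipeline-bbd"))
  fits <- lapply(c("Y1", "Y2", "Y4"), function(r)
    fit_release_surface(bbd, r))
  names(fits) <- c("Y1", "Y2", "Y4")

  # 2. Optimization against the reference release targets
  target <- reference_profile()
  opt <- optimize_composition(fits, target$pct_released)

  # 3. Dissolution similarity of the printed profiles
  releases <- donepezil_release_inputs()
  f2 <- f2_similarity(reference_profile(), optimized_profile())

  # 4. PK simulation, XR and IR
  cfg_xr <- absorption_config(release = releases$test)
  cfg_ir <- absorption_config(release = release_input("ir_first_order"))
  sim_xr <- simulate_absorption(cfg_xr, duration_h, dt_h)
  sim_ir <- simulate_absorption(cfg_ir, duration_h, dt_h)

  # 5. AFE validation on a pseudo-observed clinical set
  clinical <- make_clinical_dataset(cfg_ir,
                                    seed = derive_seed(seed, "pipeline-clin"),
                                    duration_h = duration_h, dt_h = dt_h)
  validation <- afe(clinical)

  # 6. Parameter sensitivity ranking
  psa <- lapply(psa_params, function(p) run_psa(cfg_xr, p,
                                                duration_h = duration_h,
                                                dt_h = dt_h))
  ranking <- rank_parameters(psa)

  # 7. Virtual bioequivalence
  vbe <- run_vbe_study(releases$test, releases$reference,
                       config = cfg_xr,
                       n_subjects = n_subjects, n_trials = n_trials,
                       seed = derive_seed(seed, "pipeline-vbe"),
                       duration_h = duration_h, dt_h = dt_h)

  summary <- tibble::tibble(
    f2 = f2$f2,
    opt_HPMC100 = opt$composition[["HPMC100"]],
    opt_HPMC4000 = opt$composition[["HPMC4000"]],
    opt_NaCMC = opt$composition[["NaCMC"]],
    fa_xr_pct = sim_xr$fa_total, fa_ir_pct = sim_ir$fa_total,
    cmax_xr = sim_xr$pk$cmax, auc_xr = sim_xr$pk$auc_0_t,
    afe_cmax = validation$afe[validation$metric == "cmax"],
    afe_auc = validation$afe[validation$metric == "auc_0_t"],
    vbe_n_pass = vbe$n_pass, vbe_n_trials = vbe$n_trials,
    vbe_tier = vbe$tier
  )
  out <- structure(
    list(doe = list(data = bbd, fits = fits), optimization = opt,
         dissolution = list(f2 = f2, releases = releases),
         pk = list(xr = sim_xr, ir = sim_ir),
         validation = validation, psa = list(results = psa,
                                             ranking = ranking),
         vbe = vbe, summary = summary, seed = seed),
    class = "formsim_pipeline"
  )
  if (!is.null(out_dir)) write_pipeline_report(out, out_dir)
  out
}

write_pipeline_report <- function(pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    seed = pipeline$seed,
    summary = as.list(pipeline$summary),
    optimization = list(
      composition = as.list(pipeline$optimization$composition),
      predicted = pipeline$optimization$predicted,
      target = pipeline$optimization$target,
      objective = pipeline$optimization$objective
    ),
    f2 = as.list(pipeline$dissolution$f2),
    validation = lapply(seq_len(nrow(pipeline$validation)), function(i)
      as.list(pipeline$validation[i, ])),
    psa_ranking = lapply(seq_len(nrow(pipeline$psa$ranking)), function(i)
      as.list(pipeline$psa$ranking[i, ])),
    vbe = list(
      n_pass = pipeline$vbe$n_pass, n_trials = pipeline$vbe$n_trials,
      tier = pipeline$vbe$tier,
      trials = lapply(seq_len(nrow(pipeline$vbe$trials)), function(i)
        as.list(pipeline$vbe$trials[i, ]))
    )
  )
  jsonlite::write_json(report, file.path(out_dir, "pipeline_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(pipeline$doe$data),
                   file.path(out_dir, "bbd_dataset.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(pipeline$pk$xr$profile),
                   file.path(out_dir, "xr_simulation.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.formsim_pipeline <- function(x, ...) {
  s <- x$summary
  cat("<formsim_pipeline>\n")
  cat(sprintf("  f2 (reference vs optimized): %.1f\n", s$f2))
  cat(sprintf("  optimized composition: HPMC100 %.1f / HPMC4000 %.1f / NaCMC %.1f %%w/w\n",
              s$opt_HPMC100, s$opt_HPMC4000, s$opt_NaCMC))
  cat(sprintf("  fa: XR %.1f%%, IR %.1f%%\n", s$fa_xr_pct, s$fa_ir_pct))
  cat(sprintf("  AFE: Cmax %.3f, AUC %.3f\n", s$afe_cmax, s$afe_auc))
  cat(sprintf("  VBE: %d/%d trials pass -> %s risk\n",
              s$vbe_n_pass, s$vbe_n_trials, s$vbe_tier))
  invisible(x)
}
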