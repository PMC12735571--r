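test_that("noiseless design responses recover the generating surfaces", {
  dat <- make_bbd_dataset(sigma = 0, seed = 2)
  expect_equal(nrow(dat), 17L)
  truth <- attr(dat, "truth")
  fit <- fit_release_surface(dat, "Y1")
  for (term in names(truth$Y1$coefficients)) {
    expect_equal(coef(fit$full_fit)[[term]],
                 truth$Y1$coefficients[[term]], tolerance = 1e-6)
  }
})

test_that("the default truth puts the center-point 1 h release near 22%", {
  dat <- make_bbd_dataset(sigma = 1, seed = 8)
  center <- dat[13:17, ]
  expect_lt(abs(mean(center$Y1) - 21.95), 2.5)
})

test_that("design generation is a pure function of the seed", {
  a <- make_bbd_dataset(sigma = 1, seed = 5)
  b <- make_bbd_dataset(sigma = 1, seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))
  d <- withr::local_tempdir()
  make_bbd_dataset(sigma = 1, seed = 5, out_dir = d)
  expect_true(file.exists(file.path(d, "bbd_design.csv")))
  expect_true(file.exists(file.path(d, "bbd_responses.csv")))
})

test_that("noiseless dissolution vessels lie exactly on the truth curve", {
  truth <- list(ref = weibull_release(77, 1, scale1 = 2, shape1 = 1.5))
  dat <- make_dissolution_dataset(truth, n_vessels = 1, sigma = 0, seed = 1)
  expect_equal(dat$pct_released,
               eval_weibull_release(truth$ref, dat$time_h))
})

test_that("generated vessels satisfy the profile invariants", {
  truth <- list(a = weibull_release(85, 0.6, 1, 1.5, 8, 1))
  dat <- make_dissolution_dataset(truth, n_vessels = 6, sigma = 2, seed = 3)
  expect_true(all(dat$pct_released >= 0 & dat$pct_released <= 100))
  for (v in split(dat, dat$vessel_id)) {
    expect_true(all(diff(v$pct_released) >= 0))
  }
  # consumable by the fitter and f2 without modification
  expect_s3_class(fit_weibull_release(dat), "weibull_fit")
})

test_that("truth curves offset by 10 points generate f2 near 50", {
  base <- weibull_release(80, 1, scale1 = 2, shape1 = 1.2)
  times <- c(0.5, 1, 2.5, 5, 13)
  ref <- profile_tbl(times, eval_weibull_release(base, times))
  tst <- profile_tbl(times, eval_weibull_release(base, times) - 10)
  expect_equal(round(f2_similarity(ref, tst, cap_85 = FALSE)$f2), 50)
})

test_that("same-truth vessels give similar mean profiles at 1% noise", {
  truth <- weibull_release(77, 1, scale1 = 2, shape1 = 1.5)
  dat <- make_dissolution_dataset(list(r = truth, t = truth),
                                  n_vessels = 12, sigma = 1, seed = 10)
  res <- f2_similarity(dat[dat$formulation == "r", ],
                       dat[dat$formulation == "t", ])
  expect_gt(res$f2, 50)
})

test_that("an unperturbed clinical dataset validates with AFE exactly 1", {
  clin <- make_clinical_dataset(fx_cfg_ir(), n_studies = 2,
                                perturbation = 0, seed = 1,
                                duration_h = FAST_DUR, dt_h = FAST_DT)
  res <- afe(clin)
  expect_equal(res$afe, c(1, 1), tolerance = 1e-12)
})

test_that("systematically faster clearance in the observations biases AFE up", {
  cfg <- fx_cfg_ir()
  baseline <- fx_sim_ir()
  obs_cfg <- modify_config(modify_config(cfg, "vmax_cyp3a4", 1.3),
                           "vmax_cyp2d6", 1.3)
  obs <- simulate_absorption(obs_cfg, FAST_DUR, FAST_DT)
  v <- tibble::tibble(
    study_id = 1, metric = c("cmax", "auc_0_t"),
    predicted = c(baseline$pk$cmax, baseline$pk$auc_0_t),
    observed = c(obs$pk$cmax, obs$pk$auc_0_t)
  )
  res <- afe(v)
  # predictions exceed the faster-clearing "observations"
  expect_true(all(res$afe > 1))
})

test_that("nine mildly perturbed studies stay inside the AFE band", {
  clin <- make_clinical_dataset(fx_cfg_ir(), n_studies = 9,
                                perturbation = 0.1, seed = 4,
                                duration_h = FAST_DUR, dt_h = FAST_DT)
  res <- afe(clin)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$afe >= 0.8 & res$afe <= 1.25))
  expect_true(all(res$pass))
})
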