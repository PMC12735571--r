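test_that("population multipliers are median-1 log-normal with stated CV", {
  # zero CV: every multiplier exactly 1
  spec0 <- variability_spec(tibble::tibble(
    parameter = variability_spec()$parameter, bsv_cv = 0, wsv_cv = 0))
  pop0 <- build_population(spec0, n = 5, seed = 3)
  expect_true(all(pop0$bsv == 1))
  expect_true(all(pop0$wsv_p1 == 1))
  expect_true(all(pop0$wsv_p2 == 1))
  # 30% CV recovers empirically at large n
  pop <- build_population(variability_spec(), n = 10000, seed = 4)
  peff <- pop[pop$parameter == "peff", ]
  cv_emp <- 100 * sd(peff$bsv) / mean(peff$bsv)
  expect_lt(abs(cv_emp - 30), 1)
  # reproducibility
  expect_identical(build_population(variability_spec(), 50, seed = 9),
                   build_population(variability_spec(), 50, seed = 9))
})

test_that("the crossover analysis matches the hand-computed 2x2 formulas", {
  # fixed synthetic table: 6 subjects, sequences TR/RT
  tbl <- tibble::tibble(
    subject = rep(1:6, each = 2),
    sequence = rep(c("TR", "RT"), each = 6),
    period = rep(1:2, 6),
    treatment = c("T", "R", "T", "R", "T", "R", "R", "T", "R", "T", "R", "T"),
    value = c(102, 95, 88, 93, 110, 104, 97, 99, 105, 112, 92, 88)
  )
  got <- be_analysis(tbl)
  # oracle: period differences within sequence (Schuirmann)
  logv <- log(tbl$value)
  d <- vapply(1:6, function(s) {
    rows <- tbl$subject == s
    logv[rows & tbl$period == 1] - logv[rows & tbl$period == 2]
  }, numeric(1))
  d_tr <- d[1:3] # sequence TR: d = T - R
  d_rt <- d[4:6] # sequence RT: d = R - T
  est <- (mean(d_tr) - mean(d_rt)) / 2
  s2 <- (sum((d_tr - mean(d_tr))^2) + sum((d_rt - mean(d_rt))^2)) / (6 - 2)
  se <- sqrt(s2 * (1 / 3 + 1 / 3)) / 2
  ci <- exp(est + c(-1, 1) * qt(0.95, 4) * se)
  expect_equal(got$gmr, exp(est), tolerance = 1e-9)
  expect_equal(c(got$ci_lower, got$ci_upper), ci, tolerance = 1e-9)
  expect_equal(got$df, 4L)
})

test_that("interval width shrinks as the crossover grows", {
  make_tbl <- function(n, sigma_w, seed) {
    withr::with_seed(seed, {
      subj <- rep(seq_len(n), each = 2)
      seqn <- rep(ifelse(seq_len(n) <= n / 2, "TR", "RT"), each = 2)
      period <- rep(1:2, n)
      trt <- ifelse((seqn == "TR") == (period == 1), "T", "R")
      u <- rnorm(n, 0, 0.3)[subj] # subject effects
      tibble::tibble(subject = subj, sequence = seqn, period = period,
                     treatment = trt,
                     value = exp(u + rnorm(2 * n, 0, sigma_w)))
    })
  }
  w12 <- be_analysis(make_tbl(12, 0.15, 8))
  w48 <- be_analysis(make_tbl(48, 0.15, 8))
  expect_lt(w48$ci_upper / w48$ci_lower, w12$ci_upper / w12$ci_lower)
})

test_that("identical formulations with no variability give GMR exactly 1", {
  spec0 <- variability_spec(tibble::tibble(
    parameter = variability_spec()$parameter, bsv_cv = 0, wsv_cv = 0))
  pop <- build_population(spec0, n = 4, seed = 1)
  rel <- fx_releases()
  tr <- run_trial(rel$reference, rel$reference, pop, fx_cfg_xr(),
                  duration_h = FAST_DUR, dt_h = FAST_DT)
  expect_equal(tr$be$gmr, c(1, 1), tolerance = 1e-9)
  expect_equal(tr$be$ci_lower, tr$be$gmr, tolerance = 1e-9)
  expect_true(tr$pass)
})

test_that("halving the releasable dose halves AUC and fails BE", {
  rel <- fx_releases()
  wb_half <- rel$reference$weibull
  wb_half$fmax <- wb_half$fmax / 2
  test_rel <- release_input("xr_weibull",
                            weibull = do.call(weibull_release,
                                              unclass(wb_half)))
  small_cv <- variability_spec(tibble::tibble(
    parameter = variability_spec()$parameter, bsv_cv = 1, wsv_cv = 1))
  pop <- build_population(small_cv, n = 4, seed = 6)
  tr <- run_trial(test_rel, rel$reference, pop, fx_cfg_xr(),
                  duration_h = FAST_DUR, dt_h = FAST_DT)
  auc <- tr$be[tr$be$metric == "auc_0_t", ]
  expect_equal(auc$gmr, 0.5, tolerance = 0.05)
  expect_false(auc$pass)
  expect_false(tr$pass)
})

test_that("risk tiers follow the 13/15 and 9/15 proportional cuts", {
  expect_equal(risk_tier(15, 15), "low")
  expect_equal(risk_tier(13, 15), "low")
  expect_equal(risk_tier(12, 15), "moderate")
  expect_equal(risk_tier(10, 15), "moderate")
  expect_equal(risk_tier(9, 15), "moderate")
  expect_equal(risk_tier(8, 15), "high")
  expect_equal(risk_tier(0, 15), "high")
})

test_that("a small study is seed-reproducible end to end", {
  rel <- fx_releases()
  run <- function() {
    run_vbe_study(rel$test, rel$reference, config = fx_cfg_xr(),
                  n_subjects = 4, n_trials = 2, seed = 17,
                  duration_h = FAST_DUR, dt_h = FAST_DT)
  }
  s1 <- run()
  s2 <- run()
  expect_identical(s1$trials, s2$trials)
  expect_s3_class(glance(s1), "tbl_df")
  expect_true(s1$tier %in% c("low", "moderate", "high"))
})

test_that("identical formulations reach full power at the starting size", {
  rel <- fx_releases()
  tiny_cv <- variability_spec(tibble::tibble(
    parameter = variability_spec()$parameter, bsv_cv = 2, wsv_cv = 2))
  pow <- sample_size_step(rel$reference, rel$reference, tiny_cv,
                          config = fx_cfg_xr(), start_n = 6, step = 6,
                          max_n = 12, power_target = 0.8, n_trials = 2,
                          seed = 2, duration_h = FAST_DUR, dt_h = FAST_DT)
  expect_equal(pow$n_required, 6)
  expect_equal(pow$curve$power[1], 1)
})
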