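test_that("weibull release evaluates the closed form", {
  wb <- weibull_release(fmax = 100, w1 = 1, scale1 = 2, shape1 = 1)
  # t = scale with shape 1: 100 * (1 - e^-1)
  expect_equal(eval_weibull_release(wb, 2), 100 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(eval_weibull_release(wb, 0), 0)
  expect_equal(eval_weibull_release(weibull_release(100, 1, 1, 1), 1e4),
               100, tolerance = 1e-9)
  # lag delays all release
  wb_lag <- weibull_release(80, 0.6, 1.5, 1.2, 6, 0.8, lag = 2)
  expect_equal(eval_weibull_release(wb_lag, c(0, 1, 2)), c(0, 0, 0))
  expect_error(eval_weibull_release(list(fmax = NaN), 1),
               class = "formsim_invalid_parameter")
})

test_that("release curves are monotone and capped at fmax", {
  set.seed(42)
  tgrid <- seq(0, 60, length.out = 400)
  for (i in 1:25) {
    wb <- weibull_release(
      fmax = runif(1, 40, 110), w1 = runif(1),
      scale1 = exp(runif(1, log(0.1), log(50))),
      shape1 = runif(1, 0.2, 5),
      scale2 = exp(runif(1, log(0.1), log(50))),
      shape2 = runif(1, 0.2, 5),
      lag = runif(1, 0, 3)
    )
    y <- eval_weibull_release(wb, tgrid)
    expect_true(all(diff(y) >= -1e-12))
    expect_true(all(y <= wb$fmax + 1e-9))
  }
})

test_that("noise-free single-phase data are recovered within 1%", {
  truth <- weibull_release(fmax = 85, w1 = 1, scale1 = 3, shape1 = 0.9)
  times <- c(0.5, 1, 2.5, 5, 8, 13, 24)
  dat <- profile_tbl(times, eval_weibull_release(truth, times))
  fit <- fit_weibull_release(dat, phases = "single")
  expect_true(fit$converged)
  for (nm in c("fmax", "scale1", "shape1")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 0.01)
  }
  # fitted curve tracks the generating curve to < 0.1 percentage points
  dense <- seq(0, 24, length.out = 200)
  expect_lt(max(abs(eval_weibull_release(fit$params, dense) -
                      eval_weibull_release(truth, dense))), 0.1)
})

test_that("all-zero profiles are flagged degenerate", {
  dat <- profile_tbl(c(1, 2, 4, 8), rep(0, 4))
  expect_warning(fit <- fit_weibull_release(dat), "degenerate")
  expect_true(fit$degenerate)
  expect_lt(fit$params$fmax, 0.5)
})

test_that("biphasic data with 1% noise fit with r2 above 0.97", {
  truth <- weibull_release(fmax = 90, w1 = 0.45, scale1 = 0.8, shape1 = 1.6,
                           scale2 = 9, shape2 = 1.1)
  times <- c(0.5, 1, 2, 3.5, 5, 8, 13, 24)
  y <- eval_weibull_release(truth, times)
  withr::with_seed(7, y <- y + rnorm(length(y), 0, 1))
  fit <- fit_weibull_release(profile_tbl(times, pmax(y, 0)),
                             phases = "double")
  expect_gt(fit$r2, 0.97)
})

test_that("a fixed plateau is honored by the fitter", {
  times <- c(0.5, 1, 2.5, 5, 13)
  dat <- profile_tbl(times, eval_weibull_release(
    weibull_release(80, 1, scale1 = 2, shape1 = 1.3), times))
  fit <- fit_weibull_release(dat, fix_fmax = 80)
  expect_equal(fit$params$fmax, 80)
  expect_lt(fit$rss, 1e-8)
})

test_that("short profiles fall back to the single-phase model", {
  fit <- fit_weibull_release(reference_profile())
  expect_identical(fit$phases, "single")
  expect_equal(fit$params$w1, 1)
  # three points, three free parameters: essentially interpolating
  expect_lt(fit$rss, 1e-6)
  expect_equal(eval_weibull_release(fit$params, c(1, 2.5, 13)),
               c(23, 58, 77), tolerance = 1e-4)
})

test_that("fits are deterministic for a fixed seed", {
  times <- c(0.5, 1, 2.5, 5, 8, 13, 24)
  truth <- weibull_release(80, 0.5, 1, 1.4, 7, 1)
  y <- eval_weibull_release(truth, times)
  withr::with_seed(11, y <- pmax(y + rnorm(length(y), 0, 0.8), 0))
  f1 <- fit_weibull_release(profile_tbl(times, y), seed = 99)
  f2_ <- fit_weibull_release(profile_tbl(times, y), seed = 99)
  expect_identical(unclass(f1$params), unclass(f2_$params))
})

test_that("tidy and glance expose parameters and diagnostics", {
  fit <- fit_weibull_release(reference_profile())
  td <- tidy(fit)
  expect_setequal(td$term, c("fmax", "w1", "scale1", "shape1", "scale2",
                             "shape2", "lag"))
  gl <- glance(fit)
  expect_true(all(c("r.squared", "rss", "n", "phases") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})
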