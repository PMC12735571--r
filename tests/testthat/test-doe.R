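test_that("the 3-factor Box-Behnken design has the expected structure", {
  d5 <- bbd_design(release_factors(), n_center = 5)
  expect_equal(nrow(d5), 17L)
  d1 <- bbd_design(release_factors(), n_center = 1)
  expect_equal(nrow(d1), 13L)
  coded <- as.matrix(d5[, paste0(release_factors()$name, "_coded")])
  # every run is an edge midpoint (two nonzero coded entries) or a center
  expect_true(all(rowSums(coded != 0) <= 2))
  expect_equal(sum(rowSums(coded != 0) == 0), 5L)
  # linear columns are mutually orthogonal in coded units
  expect_equal(crossprod(coded)[lower.tri(diag(3))], rep(0, 3))
  # actual units map center to the factor midpoints
  expect_equal(unlist(d5[17, release_factors()$name], use.names = FALSE),
               release_factors()$mid)
  expect_error(bbd_design(release_factors()[1:2, ]),
               class = "formsim_unsupported_design")
})

test_that("filler is computed q.s. to the tablet mass", {
  d <- add_filler(bbd_design(release_factors(), 1))
  expect_equal(d$lactose_pct + rowSums(d[, release_factors()$name]) +
                 100 * 23 / 750 + 0.99, rep(100, nrow(d)))
})

test_that("a noiseless quadratic surface is recovered exactly", {
  design <- bbd_design(release_factors(), 5)
  truth <- c("(Intercept)" = 43, HPMC100 = -0.67, HPMC4000 = -0.96,
             NaCMC = 1.9, "I(HPMC100^2)" = 0.007, "I(HPMC4000^2)" = 0.01,
             "I(NaCMC^2)" = -0.19)
  surf <- release_surface_from_coef(truth, response_name = "Y1")
  y <- predict(surf, design[, release_factors()$name])
  fit <- fit_release_surface(design, y)
  got <- coef(fit$full_fit)[names(truth)]
  expect_equal(unname(got), unname(truth), tolerance = 1e-8)
})

test_that("OLS coefficients match the normal-equations oracle", {
  set.seed(31)
  design <- bbd_design(release_factors(), 5)
  f <- release_factors()$name
  X <- cbind(1, as.matrix(design[, f]), as.matrix(design[, f])^2,
             design[[f[1]]] * design[[f[2]]],
             design[[f[1]]] * design[[f[3]]],
             design[[f[2]]] * design[[f[3]]])
  for (i in 1:5) {
    y <- rnorm(nrow(design), 50, 10)
    fit <- fit_release_surface(design, y)
    beta_oracle <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(coef(fit$full_fit)), unname(drop(beta_oracle)),
                 tolerance = 1e-9)
  }
})

test_that("term retention is calibrated to the significance level", {
  # truly-zero interaction terms should be retained at ~ alpha rate
  set.seed(77)
  design <- bbd_design(release_factors(), 5)
  truth <- release_surface_from_coef(
    c("(Intercept)" = 50, HPMC100 = -0.8, HPMC4000 = -1.1))
  mu <- predict(truth, design[, release_factors()$name])
  null_terms <- c("HPMC100:HPMC4000", "HPMC100:NaCMC", "HPMC4000:NaCMC")
  hits <- 0L
  n_rep <- 200
  biases <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    fit <- fit_release_surface(design, mu + rnorm(length(mu)))
    hits <- hits + sum(null_terms %in% fit$retained_terms)
    biases[r] <- coef(fit$full_fit)[["HPMC100"]] + 0.8
  }
  rate <- hits / (n_rep * length(null_terms))
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09) # ~ alpha = 0.05
  expect_lt(abs(mean(biases)), 0.02) # unbiased coefficient estimates
})

test_that("center replicates yield a pure-error variance diagnostic", {
  set.seed(13)
  design <- bbd_design(release_factors(), 5)
  y <- rnorm(17, 50, 2)
  fit <- fit_release_surface(design, y)
  expect_equal(fit$pure_error_var, var(y[13:17]))
})

test_that("published coefficient models reproduce the printed predictions", {
  ms <- donepezil_release_surfaces()
  center <- c(HPMC100 = 20, HPMC4000 = 20, NaCMC = 5)
  expect_equal(predict_release(ms$Y1, center), 21.95, tolerance = 1e-12)
  expect_equal(round(predict_release(ms$Y1, center)), 22)
  expect_equal(predict_release(ms$Y4, center), 74.9, tolerance = 1e-12)
  # constant model returns its intercept anywhere
  const <- release_surface_from_coef(c("(Intercept)" = 7.5))
  expect_equal(predict_release(const, center), 7.5)
  expect_equal(predict_release(const, c(HPMC100 = 40, HPMC4000 = 5,
                                        NaCMC = 10)), 7.5)
})

test_that("composition optimization finds a planted optimum", {
  ms <- donepezil_release_surfaces()[c("Y1", "Y2", "Y4")]
  planted <- c(HPMC100 = 18, HPMC4000 = 24, NaCMC = 9)
  target <- vapply(ms, function(m) predict_release(m, planted), numeric(1))
  opt <- optimize_composition(ms, target)
  expect_lt(opt$objective, 1e-6)
  # never leaves the factor box and beats every grid start
  f <- release_factors()
  expect_true(all(opt$composition >= f$low - 1e-9 &
                    opt$composition <= f$high + 1e-9))
  expect_true(all(opt$objective <= opt$starts$objective + 1e-9))
})

test_that("optimizing against the reference targets lands near 23% at 1 h", {
  ms <- donepezil_release_surfaces()[c("Y1", "Y2", "Y4")]
  opt <- optimize_composition(ms, c(23, 58, 77))
  expect_lt(abs(opt$predicted[1] - 23), 3)
})

test_that("a degenerate single-point box returns that point", {
  ms <- donepezil_release_surfaces()[c("Y1", "Y4")]
  bounds <- data.frame(HPMC100 = c(20, 20), HPMC4000 = c(20, 20),
                       NaCMC = c(5, 5), row.names = c("low", "high"))
  opt <- optimize_composition(ms, c(23, 77), bounds = bounds)
  expect_equal(unname(opt$composition), c(20, 20, 5))
})
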