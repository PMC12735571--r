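#' Three-factor Box-Behnken design
#'
#' Generates the 3-factor, 3-level Box-Behnken design used to screen
#' release-rate-modifying excipients (e.g. HPMC 100 cps, HPMC 4000 cps and
#' NaCMC as percent w/w of tablet mass): the 12 edge-midpoint runs — every
#' (±1, ±1) combination on each factor pair with the third factor at its
#' mid level — plus `n_center` center replicates. With 5 center replicates
#' the design has the classic 17 runs.
#'
#' @param factors Data frame with columns `name`, `low`, `mid`, `high`
#'   (actual units, e.g. percent w/w); exactly 3 rows. `mid` must be the
#'   midpoint of `low` and `high`.
#' @param n_center Number of center-point replicates (>= 1), default 5.
#'
#' @return A tibble with `run_id`, coded levels (`<name>_coded`) and actual
#'   levels (`<name>`), one row per run; attribute `"factors"` carries the
#'   factor specification.
#' @examples
#' bbd_design(release_factors())
#' @export
bbd_design <- function(factors, n_center = 5) {
  if (!is.data.frame(factors) || nrow(factors) != 3 ||
      !all(c("name", "low", "mid", "high") %in% names(factors))) {
    abort(paste("`factors` must be a 3-row data frame with columns",
                "name/low/mid/high (3-factor designs only)."),
          class = "formsim_unsupported_design")
  }
  check_number(n_center, "n_center", 1, Inf)
  for (i in 1:3) {
    if (!(factors$low[i] < factors$mid[i] && factors$mid[i] < factors$high[i])) {
      abort("Each factor needs low < mid < high.",
            class = "formsim_unsupported_design")
    }
    if (abs(factors$mid[i] - (factors$low[i] + factors$high[i]) / 2) > 1e-9) {
      abort("`mid` must equal (low + high)/2 for a Box-Behnken design.",
            class = "formsim_unsupported_design")
    }
  }
  pm <- expand.grid(a = c(-1, 1), b = c(-1, 1), KEEP.OUT.ATTRS = FALSE)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  edge <- do.call(rbind, lapply(pairs, function(pr) {
    m <- matrix(0, nrow = 4, ncol = 3)
    m[, pr[1]] <- pm$a
    m[, pr[2]] <- pm$b
    m
  }))
  coded <- rbind(edge, matrix(0, nrow = n_center, ncol = 3))
  actual <- vapply(1:3, function(j) {
    factors$mid[j] + coded[, j] * (factors$high[j] - factors$low[j]) / 2
  }, numeric(nrow(coded)))
  out <- tibble::tibble(run_id = seq_len(nrow(coded)))
  for (j in 1:3) out[[paste0(factors$name[j], "_coded")]] <- coded[, j]
  for (j in 1:3) out[[factors$name[j]]] <- actual[, j]
  attr(out, "factors") <- tibble::as_tibble(factors)
  attr(out, "n_center") <- as.integer(n_center)
  class(out) <- c("bbd_design", class(out))
  out
}

#' Default release-modifier factor specification
#'
#' Three hydrophilic polymers as percent w/w of tablet mass. The default
#' levels put the design center at 20% HPMC 100 cps, 20% HPMC 4000 cps and
#' 5% NaCMC — the optimized center-point composition — with the HPMC
#' grades spanning 0–40% (the slow-release prototype carries 40% of each)
#' and NaCMC spanning 0–10%. Levels are configurable per factor.
#'
#' @param hpmc_low,hpmc_high Low/high levels for both HPMC grades
#'   (percent w/w), default 0 and 40.
#' @param nacmc_low,nacmc_high Low/high levels for NaCMC, default 0 and
#'   10.
#' @return A 3-row tibble usable as the `factors` argument of
#'   [bbd_design()].
#' @export
release_factors <- function(hpmc_low = 0, hpmc_high = 40,
                            nacmc_low = 0, nacmc_high = 10) {
  tibble::tibble(
    name = c("HPMC100", "HPMC4000", "NaCMC"),
    low = c(hpmc_low, hpmc_low, nacmc_low),
    mid = c((hpmc_low + hpmc_high) / 2, (hpmc_low + hpmc_high) / 2,
            (nacmc_low + nacmc_high) / 2),
    high = c(hpmc_high, hpmc_high, nacmc_high)
  )
}

#' Lactose filler needed to reach a fixed tablet mass
#'
#' The diluent is added q.s. to a constant total tablet weight; it is
#' reported for each run but is never a design factor.
#'
#' @param design A [bbd_design()] tibble (actual units are percent w/w).
#' @param tablet_mass_mg Total tablet mass, default 750 mg.
#' @param fixed_pct Percent w/w committed to non-filler fixed components
#'   (drug + lubricant), default 23 mg drug / 750 mg + 0.99% magnesium
#'   stearate.
#' @return The design with `lactose_pct` and `lactose_mg` columns appended.
#' @export
add_filler <- function(design, tablet_mass_mg = 750,
                       fixed_pct = 100 * 23 / 750 + 0.99) {
  factors <- attr(design, "factors")
  poly <- rowSums(as.matrix(design[, factors$name]))
  design$lactose_pct <- 100 - fixed_pct - poly
  design$lactose_mg <- design$lactose_pct / 100 * tablet_mass_mg
  design
}

quadratic_terms <- function(fnames) {
  c("(Intercept)", fnames,
    paste0("I(", fnames, "^2)"),
    paste0(fnames[c(1, 1, 2)], ":", fnames[c(2, 3, 3)]))
}

#' Fit a quadratic response surface to one release response
#'
#' Ordinary least squares on the full 10-term quadratic polynomial (linear,
#' pure quadratic and two-way interaction terms) in actual factor units,
#' followed by per-term significance screening: terms with a t-test p-value
#' below `alpha` are retained (the intercept always is) and the model is
#' refit on the retained terms for prediction.
#'
#' @param design A [bbd_design()] tibble.
#' @param response Numeric vector of one response per run (e.g. percent
#'   released at a fixed dissolution time), or the name of a column in
#'   `design`.
#' @param response_name Label for the response, default the column name or
#'   `"Y"`.
#' @param alpha Per-term significance level for retention, default 0.05.
#'
#' @return An object of class `release_surface`: full and pruned `lm` fits,
#'   coefficient/p-value tables, `r2`, `adj_r2`, pure-error variance from
#'   the center replicates, and the factor specification. Methods: `tidy()`,
#'   `glance()`, `predict()`, `autoplot()`.
#' @export
fit_release_surface <- function(design, response, response_name = NULL,
                                alpha = 0.05) {
  factors <- attr(design, "factors")
  if (is.null(factors)) {
    abort("`design` must come from bbd_design().",
          class = "formsim_invalid_parameter")
  }
  check_number(alpha, "alpha", 1e-12, 1 - 1e-12)
  if (is.character(response) && length(response) == 1) {
    response_name <- response_name %||% response
    response <- design[[response]]
  }
  response_name <- response_name %||% "Y"
  if (length(response) != nrow(design) || any(!is.finite(response))) {
    abort("`response` must supply one finite value per run.",
          class = "formsim_invalid_parameter")
  }
  fnames <- factors$name
  dat <- as.data.frame(design[, fnames])
  dat$.y <- response
  rhs <- paste(c(fnames, paste0("I(", fnames, "^2)"),
                 paste0(fnames[c(1, 1, 2)], ":", fnames[c(2, 3, 3)])),
               collapse = " + ")
  full <- lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  if (full$rank < length(coef(full)) || anyNA(coef(full))) {
    abort("Design matrix is rank deficient for the full quadratic.",
          class = "formsim_singular_design")
  }
  # summary.lm warns on numerically perfect fits (noise-free synthetic
  # responses are a supported input); the p-values are still well defined
  sm <- suppressWarnings(summary(full)$coefficients)
  pvals <- sm[, "Pr(>|t|)"]
  retained <- setdiff(rownames(sm)[pvals < alpha], "(Intercept)")
  pruned <- if (length(retained)) {
    lm(stats::as.formula(paste(".y ~", paste(retained, collapse = " + "))),
       data = dat)
  } else {
    lm(.y ~ 1, data = dat)
  }
  coded <- as.matrix(design[, paste0(fnames, "_coded")])
  center <- rowSums(abs(coded)) == 0
  pure_error_var <- if (sum(center) >= 2) var(response[center]) else NA_real_
  structure(
    list(
      response_name = response_name,
      full_fit = full, fit = pruned,
      coefficients = coef(pruned),
      p_values = pvals,
      retained_terms = retained,
      r2 = suppressWarnings(summary(pruned)$r.squared),
      adj_r2 = suppressWarnings(summary(pruned)$adj.r.squared),
      full_r2 = suppressWarnings(summary(full)$r.squared),
      pure_error_var = pure_error_var,
      alpha = alpha,
      factors = factors
    ),
    class = "release_surface"
  )
}

#' @export
print.release_surface <- function(x, ...) {
  cat(sprintf("<release_surface> %s: %d retained terms (alpha = %g), r2 = %.4f\n",
              x$response_name, length(x$retained_terms), x$alpha, x$r2))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @rdname fit_release_surface
#' @param x,object A `release_surface`.
#' @param ... Unused.
#' @export
tidy.release_surface <- function(x, ...) {
  sm <- suppressWarnings(summary(x$full_fit)$coefficients)
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"],
    retained = rownames(sm) %in% c("(Intercept)", x$retained_terms)
  )
}

#' @rdname fit_release_surface
#' @export
glance.release_surface <- function(x, ...) {
  tibble::tibble(
    response = x$response_name,
    r.squared = x$r2, adj.r.squared = x$adj_r2,
    full.r.squared = x$full_r2,
    n_retained = length(x$retained_terms),
    pure.error.var = x$pure_error_var
  )
}

#' Build a release surface directly from known coefficients
#'
#' Constructs a `release_surface` from a named coefficient vector in actual
#' factor units — e.g. a published coefficient table — so that predictions
#' and optimization can run without refitting. Term names use the factor
#' names plus `"(Intercept)"`, `"I(<f>^2)"` and `"<f1>:<f2>"`.
#'
#' @param coefficients Named numeric vector; must include `"(Intercept)"`.
#' @param factors Factor specification as in [bbd_design()], default
#'   [release_factors()].
#' @param response_name Label for the response.
#' @return A `release_surface` usable with [predict_release()] and
#'   [optimize_composition()].
#' @examples
#' m <- release_surface_from_coef(
#'   c("(Intercept)" = 43, HPMC100 = -0.67, HPMC4000 = -0.96, NaCMC = 1.9,
#'     "I(HPMC100^2)" = 0.007, "I(HPMC4000^2)" = 0.01, "I(NaCMC^2)" = -0.19),
#'   response_name = "Y1")
#' predict_release(m, c(HPMC100 = 20, HPMC4000 = 20, NaCMC = 5))
#' @export
release_surface_from_coef <- function(coefficients,
                                      factors = release_factors(),
                                      response_name = "Y") {
  if (!"(Intercept)" %in% names(coefficients)) {
    abort("`coefficients` must include \"(Intercept)\".",
          class = "formsim_invalid_parameter")
  }
  valid <- quadratic_terms(factors$name)
  bad <- setdiff(names(coefficients), valid)
  if (length(bad)) {
    abort(paste0("Unknown terms: ", paste(bad, collapse = ", ")),
          class = "formsim_invalid_parameter")
  }
  structure(
    list(
      response_name = response_name,
      full_fit = NULL, fit = NULL,
      coefficients = coefficients,
      p_values = NULL,
      retained_terms = setdiff(names(coefficients), "(Intercept)"),
      r2 = NA_real_, adj_r2 = NA_real_, full_r2 = NA_real_,
      pure_error_var = NA_real_, alpha = NA_real_,
      factors = tibble::as_tibble(factors)
    ),
    class = "release_surface"
  )
}

# Evaluate a named quadratic coefficient vector at composition x (named).
eval_quadratic <- function(coefficients, x, fnames) {
  val <- 0
  for (term in names(coefficients)) {
    beta <- coefficients[[term]]
    if (term == "(Intercept)") {
      val <- val + beta
    } else if (term %in% fnames) {
      val <- val + beta * x[[term]]
    } else if (grepl("^I\\(.*\\^2\\)$", term)) {
      f <- sub("^I\\((.*)\\^2\\)$", "\\1", term)
      val <- val + beta * x[[f]]^2
    } else {
      fs <- strsplit(term, ":", fixed = TRUE)[[1]]
      val <- val + beta * x[[fs[1]]] * x[[fs[2]]]
    }
  }
  val
}

#' Predict release from a fitted response surface
#'
#' Polynomial evaluation of the retained terms in actual factor units.
#' Compositions outside the factor bounds are allowed with a warning
#' (extrapolation).
#'
#' @param model A `release_surface` from [fit_release_surface()] or
#'   [release_surface_from_coef()].
#' @param composition Named numeric vector (or 1-row data frame) of actual
#'   factor levels, e.g. `c(HPMC100 = 20, HPMC4000 = 20, NaCMC = 5)`.
#' @return Predicted percent released (single number).
#' @export
predict_release <- function(model, composition) {
  stopifnot(inherits(model, "release_surface"))
  if (is.data.frame(composition)) composition <- unlist(composition[1, ])
  fnames <- model$factors$name
  if (!all(fnames %in% names(composition))) {
    abort(paste("`composition` must name all factors:",
                paste(fnames, collapse = ", ")),
          class = "formsim_invalid_parameter")
  }
  x <- composition[fnames]
  if (any(!is.finite(x))) {
    abort("`composition` must be finite.", class = "formsim_invalid_parameter")
  }
  if (any(x < model$factors$low - 1e-9) || any(x > model$factors$high + 1e-9)) {
    warn("Composition is outside the design bounds; extrapolating.")
  }
  unname(eval_quadratic(as.list(model$coefficients), as.list(x), fnames))
}

#' @export
predict.release_surface <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    vapply(seq_len(nrow(newdata)),
           function(i) predict_release(object, unlist(newdata[i, ])),
           numeric(1))
  } else {
    predict_release(object, newdata)
  }
}

#' Optimize composition against a target release profile
#'
#' Finds the composition whose predicted release profile is closest (least
#' squares) to a target profile — e.g. the reference product's 23/58/77%
#' at 1/2.5/13 h — given one fitted response surface per timepoint.
#' Multi-start bounded quasi-Newton search from a deterministic grid of
#' starting points guarantees the returned objective is no worse than any
#' grid start.
#'
#' @param models Named list of `release_surface` objects, one per target
#'   timepoint (order matches `target_release`).
#' @param target_release Numeric vector of target percent released, one per
#'   model; values in \[0, 100\].
#' @param bounds Optional 2-row matrix / data frame (`low`, `high`) per
#'   factor; defaults to each model's factor bounds.
#' @param n_grid Starts per factor dimension for the multi-start grid,
#'   default 4.
#'
#' @return A list of class `composition_opt`: `composition` (named vector),
#'   `predicted` (per-timepoint predictions), `target`, `objective`, and
#'   the start-grid diagnostics.
#' @export
optimize_composition <- function(models, target_release, bounds = NULL,
                                 n_grid = 4) {
  if (length(models) < 2 || length(models) != length(target_release)) {
    abort("Need >= 2 timepoint models, one target per model.",
          class = "formsim_invalid_parameter")
  }
  if (any(target_release < 0 | target_release > 100)) {
    abort("Targets must lie in [0, 100]%.",
          class = "formsim_invalid_parameter")
  }
  factors <- models[[1]]$factors
  fnames <- factors$name
  if (is.null(bounds)) {
    lo <- factors$low
    hi <- factors$high
  } else {
    bounds <- as.data.frame(bounds)
    lo <- as.numeric(bounds["low", fnames])
    hi <- as.numeric(bounds["high", fnames])
  }
  objective <- function(x) {
    xs <- setNames(as.list(x), fnames)
    preds <- vapply(models, function(m)
      eval_quadratic(as.list(m$coefficients), xs, fnames), numeric(1))
    sum((preds - target_release)^2)
  }
  if (all(hi - lo < 1e-12)) {
    x <- setNames(lo, fnames)
    preds <- vapply(models, function(m)
      eval_quadratic(as.list(m$coefficients), as.list(x), fnames), numeric(1))
    return(structure(list(composition = x, predicted = preds,
                          target = target_release, objective = objective(lo),
                          starts = tibble::tibble()),
                     class = "composition_opt"))
  }
  grid_1d <- lapply(seq_along(fnames), function(j) {
    if (hi[j] - lo[j] < 1e-12) lo[j] else
      seq(lo[j], hi[j], length.out = n_grid)
  })
  starts <- as.matrix(expand.grid(grid_1d, KEEP.OUT.ATTRS = FALSE))
  colnames(starts) <- fnames
  results <- lapply(seq_len(nrow(starts)), function(i) {
    tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lo + 1e-12 * 0, upper = hi,
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
  })
  results <- purrr::compact(results)
  if (!length(results)) {
    abort("All optimization starts failed.",
          class = "formsim_optimization_failure")
  }
  vals <- vapply(results, function(r) r$value, numeric(1))
  best <- results[[which.min(vals)]]
  x <- pmin(pmax(best$par, lo), hi)
  names(x) <- fnames
  preds <- vapply(models, function(m)
    eval_quadratic(as.list(m$coefficients), as.list(x), fnames), numeric(1))
  structure(
    list(composition = x, predicted = preds, target = target_release,
         objective = sum((preds - target_release)^2),
         starts = tibble::tibble(
           start = seq_len(nrow(starts)),
           objective = vapply(seq_len(nrow(starts)),
                              function(i) objective(starts[i, ]), numeric(1))
         )),
    class = "composition_opt"
  )
}

#' @export
print.composition_opt <- function(x, ...) {
  cat("<composition_opt>\n  composition:",
      paste(sprintf("%s = %.3g", names(x$composition), x$composition),
            collapse = ", "), "\n")
  cat("  predicted:", paste(sprintf("%.2f", x$predicted), collapse = ", "),
      " target:", paste(sprintf("%.0f", x$target), collapse = ", "), "\n")
  cat(sprintf("  objective (SS): %.4g\n", x$objective))
  invisible(x)
}

#' @rdname optimize_composition
#' @param x A `composition_opt`.
#' @param ... Unused.
#' @export
tidy.composition_opt <- function(x, ...) {
  tibble::tibble(
    factor = names(x$composition),
    level = unname(x$composition)
  )
}

#' Published Y1/Y4 release-surface coefficient sets
#'
#' Retained-term quadratic coefficients (actual percent-w/w units) for the
#' donepezil extended-release screening responses: percent released at 1 h
#' (Y1), 2.5 h (Y2), 5 h (Y3) and 13 h (Y4). Evaluating the Y1 model at the
#' center composition (20, 20, 5) gives 21.95 -> 22% released at 1 h.
#'
#' @return Named list of four `release_surface` objects (`Y1`..`Y4`).
#' @export
donepezil_release_surfaces <- function() {
  f <- release_factors()
  list(
    Y1 = release_surface_from_coef(c(
      "(Intercept)" = 43, HPMC100 = -0.67, HPMC4000 = -0.96, NaCMC = 1.9,
      "I(HPMC100^2)" = 0.007, "I(HPMC4000^2)" = 0.01, "I(NaCMC^2)" = -0.19
    ), f, "Y1"),
    Y2 = release_surface_from_coef(c(
      "(Intercept)" = 92, HPMC100 = -0.73, HPMC4000 = -1.37, NaCMC = 0.8,
      "I(HPMC4000^2)" = 0.02
    ), f, "Y2"),
    Y3 = release_surface_from_coef(c(
      "(Intercept)" = 91.8, HPMC100 = -0.72, HPMC4000 = -1.36, NaCMC = 0.02,
      "I(HPMC4000^2)" = 0.02
    ), f, "Y3"),
    Y4 = release_surface_from_coef(c(
      "(Intercept)" = 92, "HPMC100:HPMC4000" = -0.034,
      "I(HPMC100^2)" = -0.01, "I(NaCMC^2)" = 0.02
    ), f, "Y4")
  )
}
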