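# Internal helpers shared across modules.

# Deterministic child seed for a named stream. Keeps every derived seed a
# valid 32-bit integer regardless of the user's base seed.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(as.character(stream))
  h <- as.double(seed) %% 2147483629
  for (ch in chars) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# Evaluate `code` under a local RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "formsim_invalid_parameter")
  }
  if (x < lower || x > upper || (!allow_zero && x == 0)) {
    abort(sprintf("`%s` = %g is outside [%g, %g].", name, x, lower, upper),
          class = "formsim_invalid_parameter")
  }
  invisible(x)
}

# Resolve a dissolution profile argument: a data frame with time/release
# columns (default `time_h`, `pct_released`, optional `vessel_id`).
as_profile <- function(data, time = "time_h", released = "pct_released",
                       vessel = "vessel_id", arg = "data") {
  if (!is.data.frame(data)) {
    abort(sprintf("`%s` must be a data frame of dissolution points.", arg),
          class = "formsim_invalid_parameter")
  }
  for (col in c(time, released)) {
    if (!col %in% names(data)) {
      abort(sprintf("`%s` must contain a `%s` column.", arg, col),
            class = "formsim_invalid_parameter")
    }
  }
  out <- tibble::tibble(
    time_h = as.double(data[[time]]),
    pct_released = as.double(data[[released]])
  )
  if (vessel %in% names(data)) out$vessel_id <- data[[vessel]]
  if (any(!is.finite(out$time_h)) || any(!is.finite(out$pct_released))) {
    abort(sprintf("`%s` contains non-finite values.", arg),
          class = "formsim_invalid_parameter")
  }
  if (any(out$time_h < 0)) {
    abort(sprintf("`%s` has negative times.", arg),
          class = "formsim_invalid_parameter")
  }
  if (any(out$pct_released < 0 | out$pct_released > 110)) {
    abort(sprintf("`%s` has release values outside [0, 110]%%.", arg),
          class = "formsim_invalid_parameter")
  }
  split_cols <- if ("vessel_id" %in% names(out)) out$vessel_id else
    rep(1L, nrow(out))
  for (grp in split(out$time_h, split_cols)) {
    if (is.unsorted(grp, strictly = TRUE)) {
      abort(sprintf("`%s` times must be strictly increasing per vessel.", arg),
            class = "formsim_invalid_parameter")
    }
  }
  out
}
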