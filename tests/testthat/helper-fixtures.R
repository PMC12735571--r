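# Shared fixtures, memoized so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# Weibull release inputs fit to the built-in three-point profiles.
fx_releases <- function() memo("releases", donepezil_release_inputs())

# Baseline XR / IR configurations.
fx_cfg_xr <- function() {
  memo("cfg_xr", absorption_config(release = fx_releases()$reference))
}
fx_cfg_ir <- function() {
  memo("cfg_ir", absorption_config(release = release_input("ir_first_order")))
}

# Coarse simulation settings used where grid resolution is not under test.
FAST_DUR <- 48
FAST_DT <- 0.2

fx_sim_ir <- function() {
  memo("sim_ir", simulate_absorption(fx_cfg_ir(), FAST_DUR, FAST_DT))
}
fx_sim_xr <- function() {
  memo("sim_xr", simulate_absorption(fx_cfg_xr(), FAST_DUR, FAST_DT))
}

# Direct one-line f2 evaluation used as the oracle.
f2_oracle <- function(R, T_) {
  50 * log10(100 * (1 + mean((R - T_)^2))^(-0.5))
}

profile_tbl <- function(times, released, vessel = NULL) {
  out <- tibble::tibble(time_h = times, pct_released = released)
  if (!is.null(vessel)) out$vessel_id <- vessel
  out
}
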