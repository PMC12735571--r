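#' Tablet hydration percent
#'
#' Water uptake of a hydrophilic matrix tablet, relative to its dried mass:
#' `100 * (wet - dry) / dry`. Slow-release high-polymer matrices typically
#' gain ~300%, fast-release ones ~175%.
#'
#' @param wet_g,dry_g Wet and post-drying tablet weights (g), positive;
#'   `dry_g <= wet_g`.
#' @return Hydration, percent of dry weight.
#' @examples
#' hydration_pct(wet_g = 2, dry_g = 0.5) # 300
#' @export
hydration_pct <- function(wet_g, dry_g) {
  stopifnot(length(wet_g) == length(dry_g))
  if (any(!is.finite(wet_g)) || any(!is.finite(dry_g)) ||
      any(wet_g <= 0) || any(dry_g < 0)) {
    abort("Weights must be finite and positive.",
          class = "formsim_invalid_parameter")
  }
  if (any(dry_g == 0)) {
    abort("`dry_g` must be > 0 (division by dry weight).",
          class = "formsim_division_error")
  }
  if (any(dry_g > wet_g)) {
    abort("`dry_g` cannot exceed `wet_g`.",
          class = "formsim_invalid_parameter")
  }
  100 * (wet_g - dry_g) / dry_g
}

#' Tablet erosion percent
#'
#' Matrix mass loss during dissolution, relative to the initial tablet
#' weight: `100 * (initial - dry) / initial`. A dry weight above the
#' initial weight (weight-gain artifact, e.g. buffer salt deposition)
#' yields a negative value with a warning rather than an error.
#'
#' @param initial_g,dry_g Initial and post-drying tablet weights (g),
#'   positive.
#' @return Erosion, percent of initial weight.
#' @examples
#' erosion_pct(initial_g = 0.75, dry_g = 0.6) # 20
#' @export
erosion_pct <- function(initial_g, dry_g) {
  stopifnot(length(initial_g) == length(dry_g))
  if (any(!is.finite(initial_g)) || any(!is.finite(dry_g)) ||
      any(initial_g <= 0) || any(dry_g <= 0)) {
    abort("Weights must be finite and positive.",
          class = "formsim_invalid_parameter")
  }
  if (any(dry_g > initial_g)) {
    warn("Dry weight exceeds initial weight; reporting negative erosion.")
  }
  100 * (initial_g - dry_g) / initial_g
}

#' Gel strength from a texture-analyzer penetration point
#'
#' Converts a single probe-penetration reading on the hydrated gel layer to
#' a pressure-like gel strength: `G = 0.0098 * F / (x * rp)` (MPa), where
#' `F` is the force in grams-force (0.0098 converts gram-force to newtons),
#' `x` the penetration depth (mm) and `rp` the probe radius (mm, default
#' 7.0). `formula_variant = "force_times_depth"` provides the alternative
#' literal reading `G = 0.0098 * F * x / rp` for sensitivity checks; the
#' default keeps the stated force-per-displacement semantics so that units
#' resolve toward pressure.
#'
#' @param force_g Force at probe penetration, grams-force, >= 0.
#' @param depth_mm Penetration depth, mm, > 0.
#' @param probe_radius_mm Probe radius, mm, default 7.0.
#' @param formula_variant `"force_over_depth"` (default) or
#'   `"force_times_depth"`.
#' @return Gel strength in MPa.
#' @examples
#' gel_strength(force_g = 100, depth_mm = 1) # 0.14 MPa
#' @export
gel_strength <- function(force_g, depth_mm, probe_radius_mm = 7,
                         formula_variant = c("force_over_depth",
                                             "force_times_depth")) {
  formula_variant <- match.arg(formula_variant)
  stopifnot(length(force_g) == length(depth_mm))
  if (any(!is.finite(force_g)) || any(force_g < 0)) {
    abort("`force_g` must be finite and >= 0.",
          class = "formsim_invalid_parameter")
  }
  if (any(!is.finite(depth_mm)) || any(depth_mm <= 0)) {
    abort("`depth_mm` must be > 0.", class = "formsim_division_error")
  }
  if (!is.finite(probe_radius_mm) || probe_radius_mm <= 0) {
    abort("`probe_radius_mm` must be > 0.",
          class = "formsim_division_error")
  }
  switch(formula_variant,
    force_over_depth = 0.0098 * force_g / (depth_mm * probe_radius_mm),
    force_times_depth = 0.0098 * force_g * depth_mm / probe_radius_mm
  )
}

#' Characterize tablet matrix records
#'
#' Data-frame interface over [hydration_pct()], [erosion_pct()] and
#' [gel_strength()]: appends computed columns to a table of raw weight
#' and/or texture measurements.
#'
#' @param data Data frame. Hydration/erosion need `initial_g`, `wet_g`,
#'   `dry_g`; gel strength needs `force_g` and `depth_mm`. Extra columns
#'   (e.g. `formulation_id`, `time_h`, `rpm`) pass through.
#' @param probe_radius_mm Probe radius for gel strength, default 7 mm.
#' @return The input tibble with `hydration_pct`, `erosion_pct` and/or
#'   `gel_strength_mpa` columns appended, as the inputs allow.
#' @export
characterize_matrix <- function(data, probe_radius_mm = 7) {
  out <- tibble::as_tibble(data)
  if (all(c("wet_g", "dry_g") %in% names(out))) {
    out$hydration_pct <- hydration_pct(out$wet_g, out$dry_g)
  }
  if (all(c("initial_g", "dry_g") %in% names(out))) {
    out$erosion_pct <- erosion_pct(out$initial_g, out$dry_g)
  }
  if (all(c("force_g", "depth_mm") %in% names(out))) {
    out$gel_strength_mpa <- gel_strength(out$force_g, out$depth_mm,
                                         probe_radius_mm)
  }
  out
}
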