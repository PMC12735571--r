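#' Drug physicochemical and biopharmaceutic parameters
#'
#' Bundles the compound-level inputs of the oral absorption model. Defaults
#' are the donepezil values used throughout the package: MW 379.5 g/mol,
#' logP 4.2, blood:plasma ratio 0.78, 4% unbound in plasma, measured
#' solubility 31/47/52 mg/mL at pH 2/4.5/6.8, pKa 8.12 (basic) with a
#' fitted solubilization factor of 616, effective permeability
#' 3.1e-4 cm/s, 23 mg dose.
#'
#' Luminal saturation is interpolated piecewise-linearly from the measured
#' pH/solubility triplet (clamped outside its range). The solubilization
#' factor is carried for reference but not multiplied into the triplet,
#' which is already a direct solubility measurement; at the 23 mg dose
#' saturation never binds.
#'
#' @param molecular_weight g/mol. @param logp Octanol:water log partition.
#' @param blood_plasma_ratio Unitless. @param fu_plasma Fraction unbound
#' (0, 1]. @param solubility_ph,solubility_mg_ml Paired vectors defining
#' the pH-solubility curve. @param pka_base Basic pKa. @param sol_factor
#' Salt solubilization multiplier (reference only). @param peff_cm_s
#' Effective intestinal permeability, cm/s. @param dose_mg Oral dose, mg.
#' @return A list of class `drug_params`.
#' @export
drug_params <- function(molecular_weight = 379.5, logp = 4.2,
                        blood_plasma_ratio = 0.78, fu_plasma = 0.04,
                        solubility_ph = c(2, 4.5, 6.8),
                        solubility_mg_ml = c(31, 47, 52),
                        pka_base = 8.12, sol_factor = 616,
                        peff_cm_s = 3.1e-4, dose_mg = 23) {
  check_number(molecular_weight, "molecular_weight", 1e-6, Inf)
  check_number(blood_plasma_ratio, "blood_plasma_ratio", 1e-6, Inf)
  check_number(fu_plasma, "fu_plasma", 1e-9, 1)
  check_number(peff_cm_s, "peff_cm_s", 0, Inf)
  check_number(dose_mg, "dose_mg", 0, Inf)
  stopifnot(length(solubility_ph) == length(solubility_mg_ml),
            all(is.finite(solubility_mg_ml)), all(solubility_mg_ml > 0))
  structure(
    list(molecular_weight = molecular_weight, logp = logp,
         blood_plasma_ratio = blood_plasma_ratio, fu_plasma = fu_plasma,
         solubility_ph = solubility_ph,
         solubility_mg_ml = solubility_mg_ml,
         pka_base = pka_base, sol_factor = sol_factor,
         peff_cm_s = peff_cm_s, dose_mg = dose_mg),
    class = "drug_params"
  )
}

#' Michaelis-Menten enzyme kinetics with liver scale-up
#'
#' In vitro microsomal kinetics scaled to whole-liver capacity via MPPGL
#' (mg microsomal protein per g liver) and liver mass. Defaults carry the
#' donepezil CYP kinetics: CYP2D6 Vmax 125 ng/min/mg, Km 47 umol/L; CYP3A4
#' Vmax 89 ng/min/mg, Km 44 umol/L with scale factor 5.0. The CYP2D6 scale
#' factor default (6.0) was calibrated once so the model's linear plasma
#' clearance matches published donepezil clearance (~9 L/h, terminal
#' half-life ~70 h); see the methods vignette.
#'
#' @param enzyme `"CYP3A4"` or `"CYP2D6"`.
#' @param vmax ng/min/mg microsomal protein. @param km umol/L.
#' @param sf Unitless scale factor multiplying Vmax.
#' @param mppgl mg microsomal protein per g liver, default 32.
#' @param liver_g Liver mass, g, default 1800.
#' @return A list of class `enzyme_kinetics`; `vmax_mg_h` holds the scaled
#'   whole-liver capacity in mg/h.
#' @export
enzyme_kinetics <- function(enzyme, vmax, km, sf = 1,
                            mppgl = 32, liver_g = 1800) {
  enzyme <- match.arg(enzyme, c("CYP3A4", "CYP2D6"))
  check_number(vmax, "vmax", 1e-12, Inf)
  check_number(km, "km", 1e-12, Inf)
  check_number(sf, "sf", 0, Inf)
  structure(
    list(enzyme = enzyme, vmax = vmax, km = km, sf = sf,
         mppgl = mppgl, liver_g = liver_g,
         # ng/min/mg * mg protein -> ng/min -> mg/h
         vmax_mg_h = vmax * mppgl * liver_g * 60 / 1e6),
    class = "enzyme_kinetics"
  )
}

#' Donepezil CYP enzyme set
#' @return List of two [enzyme_kinetics()] objects (`cyp3a4`, `cyp2d6`).
#' @param sf_cyp2d6 CYP2D6 scale factor (calibrated default 6.0).
#' @param sf_cyp3a4 CYP3A4 scale factor, default 5.0.
#' @export
donepezil_enzymes <- function(sf_cyp2d6 = 6.0, sf_cyp3a4 = 5.0) {
  list(
    cyp3a4 = enzyme_kinetics("CYP3A4", vmax = 89, km = 44, sf = sf_cyp3a4),
    cyp2d6 = enzyme_kinetics("CYP2D6", vmax = 125, km = 47, sf = sf_cyp2d6)
  )
}

#' Fasted gastrointestinal physiology
#'
#' Nine sequential lumen compartments (stomach, duodenum, two jejunal,
#' three ileal, caecum, ascending colon) with first-order transit. Values
#' are documented fasted-human defaults of this package: stomach transit
#' (gastric emptying) 0.25 h; small-intestinal transit ~3.3 h split over
#' six segments; slower caecal/colonic transit. `absorption_scale` is the
#' segment-specific multiplier on the permeability-driven absorption rate
#' constant `ka = 2 * Peff * scale / radius`; it is zero in the stomach and
#' reduced in the colon (smaller absorptive surface per volume).
#'
#' @param stomach_transit_h Stomach (gastric emptying) transit time, h.
#' @param colon_absorption_scale Ascending-colon absorption scale
#'   (default 0.3; caecum uses 4/3 of it).
#' @return A tibble of class `gi_physiology` with one row per segment:
#'   `segment`, `transit_h`, `volume_ml`, `ph`, `radius_cm`,
#'   `absorption_scale`.
#' @export
gi_physiology <- function(stomach_transit_h = 0.25,
                          colon_absorption_scale = 0.3) {
  check_number(stomach_transit_h, "stomach_transit_h", 1e-6, Inf)
  out <- tibble::tibble(
    segment = c("stomach", "duodenum", "jejunum1", "jejunum2",
                "ileum1", "ileum2", "ileum3", "caecum", "asc_colon"),
    transit_h = c(stomach_transit_h, 0.26, 0.93, 0.74, 0.58, 0.42, 0.29,
                  4.5, 13.5),
    volume_ml = c(50, 42, 150, 120, 95, 75, 55, 50, 50),
    ph = c(1.3, 6.0, 6.2, 6.4, 6.6, 6.9, 7.4, 6.4, 6.8),
    radius_cm = c(10, 1.53, 1.45, 1.29, 1.13, 0.98, 0.82, 3.39, 2.41),
    absorption_scale = c(0, 0.55, 0.55, 0.5, 0.45, 0.4, 0.4,
                         colon_absorption_scale * 4 / 3,
                         colon_absorption_scale)
  )
  class(out) <- c("gi_physiology", class(out))
  out
}

#' Lumped two-compartment disposition
#'
#' Systemic disposition behind the absorption model: a central compartment
#' with well-stirred-liver elimination plus one peripheral compartment.
#' Defaults were calibrated once against published donepezil disposition
#' (immediate-release Tmax 3-5 h, terminal half-life ~70 h) and are not
#' tuned per simulation.
#'
#' @param vc_l_kg Central volume, L/kg. @param k12,k21 Inter-compartment
#'   rate constants, 1/h. @param q_hepatic_l_h Hepatic blood flow, L/h.
#' @param body_weight_kg Body weight, kg.
#' @return A list of class `disposition_params`.
#' @export
disposition_params <- function(vc_l_kg = 6.5, k12 = 0.025, k21 = 0.035,
                               q_hepatic_l_h = 90, body_weight_kg = 70) {
  for (nm in c("vc_l_kg", "k12", "k21", "q_hepatic_l_h", "body_weight_kg")) {
    check_number(get(nm), nm, 1e-9, Inf)
  }
  structure(
    list(vc_l_kg = vc_l_kg, k12 = k12, k21 = k21,
         q_hepatic_l_h = q_hepatic_l_h, body_weight_kg = body_weight_kg),
    class = "disposition_params"
  )
}

#' Dosage-form release input
#'
#' Either an extended-release Weibull schedule (`"xr_weibull"`, the direct
#' in vitro input) or first-order immediate release (`"ir_first_order"`,
#' default rate 8/h, i.e. >= 85% released within 15 min).
#'
#' @param mode `"xr_weibull"` or `"ir_first_order"`.
#' @param weibull A [weibull_release()] (required for XR).
#' @param ir_rate_constant First-order release rate, 1/h (IR mode).
#' @return A list of class `release_input`.
#' @export
release_input <- function(mode = c("xr_weibull", "ir_first_order"),
                          weibull = NULL, ir_rate_constant = 8) {
  mode <- match.arg(mode)
  if (mode == "xr_weibull") {
    if (!inherits(weibull, "weibull_release")) {
      abort("XR mode needs a weibull_release() in `weibull`.",
            class = "formsim_invalid_parameter")
    }
  } else {
    check_number(ir_rate_constant, "ir_rate_constant", 1e-9, Inf)
  }
  structure(list(mode = mode, weibull = weibull,
                 ir_rate_constant = ir_rate_constant),
            class = "release_input")
}

#' Assemble a full absorption-simulation configuration
#'
#' @param drug [drug_params()]. @param gi [gi_physiology()].
#' @param enzymes List with `cyp3a4` and `cyp2d6` [enzyme_kinetics()].
#' @param disposition [disposition_params()]. @param release
#'   [release_input()].
#' @return A list of class `absorption_config`.
#' @examples
#' cfg <- absorption_config(release = release_input("ir_first_order"))
#' @export
absorption_config <- function(drug = drug_params(),
                              gi = gi_physiology(),
                              enzymes = donepezil_enzymes(),
                              disposition = disposition_params(),
                              release = release_input("ir_first_order")) {
  stopifnot(inherits(drug, "drug_params"),
            inherits(gi, "gi_physiology"),
            inherits(disposition, "disposition_params"),
            inherits(release, "release_input"))
  stopifnot(all(c("cyp3a4", "cyp2d6") %in% names(enzymes)))
  structure(list(drug = drug, gi = gi, enzymes = enzymes,
                 disposition = disposition, release = release),
            class = "absorption_config")
}

#' Read / write an absorption configuration as JSON
#'
#' The JSON mirrors the configuration blocks (`drug`, `gi`, `enzymes`,
#' `disposition`, `release`) with units as documented in each constructor.
#'
#' @param config An `absorption_config`. @param path File path.
#' @return `read_absorption_config()` returns an `absorption_config`;
#'   `write_absorption_config()` returns `path` invisibly.
#' @export
write_absorption_config <- function(config, path) {
  stopifnot(inherits(config, "absorption_config"))
  plain <- list(
    drug = unclass(config$drug),
    gi = as.data.frame(config$gi),
    enzymes = lapply(config$enzymes, unclass),
    disposition = unclass(config$disposition),
    release = list(
      mode = config$release$mode,
      weibull = if (!is.null(config$release$weibull))
        unclass(config$release$weibull),
      ir_rate_constant = config$release$ir_rate_constant
    )
  )
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_absorption_config
#' @export
read_absorption_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  gi <- tibble::as_tibble(x$gi)
  class(gi) <- c("gi_physiology", class(gi))
  release <- if (x$release$mode == "xr_weibull") {
    release_input("xr_weibull",
                  weibull = do.call(weibull_release, as.list(x$release$weibull)))
  } else {
    release_input("ir_first_order",
                  ir_rate_constant = x$release$ir_rate_constant)
  }
  absorption_config(
    drug = do.call(drug_params, x$drug[setdiff(names(x$drug),
                                               character(0))]),
    gi = gi,
    enzymes = list(
      cyp3a4 = do.call(enzyme_kinetics,
                       x$enzymes$cyp3a4[c("enzyme", "vmax", "km", "sf",
                                          "mppgl", "liver_g")]),
      cyp2d6 = do.call(enzyme_kinetics,
                       x$enzymes$cyp2d6[c("enzyme", "vmax", "km", "sf",
                                          "mppgl", "liver_g")])
    ),
    disposition = do.call(disposition_params, x$disposition),
    release = release
  )
}
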