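---
title: "Methods: from response-surface formulation design to virtual bioequivalence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from response-surface formulation design to virtual bioequivalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(formsim)
```

`formsim` implements an integrated, model-informed workflow for developing
an extended-release (XR) hydrophilic-matrix tablet that is bioequivalent to
a reference product, worked end-to-end on donepezil (23 mg). This vignette
documents the models, their assumptions, the tunable parameters, and the
design decisions behind each stage, in the order the pipeline runs them.

## 1. Response-surface screening of the formulation space

Drug release from a hydrophilic matrix is governed by the gel layer that
the swellable polymers form on hydration. Three release-rate modifiers are
screened — HPMC 100 cps, HPMC 4000 cps and NaCMC, as percent w/w of a
750 mg tablet (lactose q.s. as filler, reported by `add_filler()` but never
a factor) — with a 3-factor, 3-level Box–Behnken design (BBD):
12 edge-midpoint runs plus `n_center = 5` center replicates, 17 runs in
all. The center replicates estimate pure error.

**Factor levels.** The default levels are HPMC grades 0–40% and NaCMC
0–10%, so the design center is the optimized composition
(20, 20, 5)% w/w. The low/high span follows the slow-release
(40/40/5) and fast-release prototype compositions; NaCMC's narrower range
reflects its role as a minor, nonlinear modifier of early release. All
levels are configurable through `release_factors()`.

Each dissolution response (percent released at 1, 2.5, 5 and 13 h) is fit
by ordinary least squares to the full ten-term quadratic

$$Y = \beta_0 + \sum_i \beta_i X_i + \sum_i \beta_{ii} X_i^2 +
  \sum_{i<j} \beta_{ij} X_i X_j$$

in **actual percent-w/w units**, not coded units. This choice is
deliberate: the published per-response coefficient sets
(`donepezil_release_surfaces()`) only reproduce the known center-point
release (22% at 1 h from the Y1 model evaluated at 20/20/5) when read in
actual units; in coded units the center prediction would equal the
intercept (43), which contradicts the measured value. Terms are screened
per coefficient: a term is retained when its t-test p-value is below
`alpha = 0.05` (the intercept always is), and the model is refit on the
retained set. No stepwise search is performed — the screening mirrors a
sparse per-response retained-term table, and per-term pruning keeps the
procedure deterministic and transparent.

The Y2/Y3 published coefficient sets evaluated at the center give ~62
rather than the measured 55 — printed coefficients are rounded — so only
the Y1 center check is treated as an exact anchor; the Y2/Y3 surfaces are
used as-is without forcing agreement.

**Optimization.** `optimize_composition()` minimizes the summed squared
deviation between model-predicted and target release (the reference
profile, 23/58/77% at 1/2.5/13 h) over the factor box, by multi-start
L-BFGS-B from a deterministic grid (default 4³ starts). The returned
objective is never worse than any grid start, and the optimum never leaves
the box.

## 2. Dissolution kinetics and similarity

Release curves are modeled with a double Weibull function — two Weibull
CDF phases sharing a releasable plateau `fmax` and lag:

$$R(t) = F_{max}\!\left[w_1\!\left(1-e^{-((t-l)/s_1)^{b_1}}\right) +
 (1-w_1)\!\left(1-e^{-((t-l)/s_2)^{b_2}}\right)\right]$$

This parameterization (weights `w1`/`1-w1`, shared plateau and lag)
matches the `Fmax` / `Weibscale 1 and 2` / `Weibshape 1 and 2` naming used
by oral-absorption simulators for direct in vitro release input. Fitting
uses bounded multi-start Levenberg–Marquardt (shapes in [0.2, 5], scales
in [0.05, 100] h, logistic transforms enforcing the box; a deterministic
start grid plus seeded jitter) because biphasic least-squares surfaces are
multimodal. With fewer than 7 points the fitter drops to the single-phase
model (`w1 = 1`) rather than estimate 7 parameters — this is also how the
three-point reference and optimized profiles are converted to release
inputs for the bioequivalence stage (3 free parameters, 3 points: the fit
is essentially exact, rss < 1e-6).

Profile similarity uses the f2 statistic,
$f_2 = 50\log_{10}\bigl(100[1+\tfrac1n\sum_t(R_t-T_t)^2]^{-1/2}\bigr)$,
on shared timepoints, with the standard regulatory convention of keeping
at most one point after both profiles exceed 85% released (prevents
inflating similarity where both products are fully dissolved). A uniform
10-point difference gives 49.89, rounding to the conventional threshold
of 50. Replicate-vessel uncertainty is handled by a vessel-level bootstrap
(default 2000 resamples, percentile interval, decision on the 5th
percentile) — the common conservative approach when only vessel-level
replication is available.

## 3. Matrix characterization

Hydration (water uptake relative to dried mass), erosion (mass loss
relative to initial mass) and gel strength are single-formula metrics on
raw weights and texture-analyzer readings. Gel strength is implemented as
$G = 0.0098\,F/(x\,r_p)$ MPa (force in grams-force, 0.0098 g-force→N;
penetration depth and probe radius in mm, default radius 7.0 mm). The
source equation for G is typographically ambiguous, so the alternative
literal reading is available behind `formula_variant`; the default
preserves the stated force-per-displacement semantics, and the default
radius is the equation's stated 7.0 mm even though the probe is described
elsewhere as 10 mm in diameter.

## 4. The oral absorption and disposition model

`simulate_absorption()` integrates a compartmental
gastrointestinal-transit (ACAT-style) model: nine sequential lumen
segments (stomach, duodenum, jejunum 1–2, ileum 1–3, caecum, ascending
colon), each holding three drug species — undissolved drug still inside
the dosage form, released solid, and dissolved drug — with first-order
transit between segments.

- **Release.** The dosage form releases drug at the hazard rate of its
  cumulative release curve, so total release tracks the in vitro Weibull
  input exactly (XR), or at a constant first-order rate (IR, default
  8 h⁻¹ ≥ 85% in 15 min, a first-order stand-in chosen to reproduce the
  observed plateau within the first 15 min).
- **Dissolution and solubility.** Released solid dissolves at 50 h⁻¹,
  throttled toward zero as the dissolved concentration approaches the
  luminal saturation interpolated from the measured pH 2/4.5/6.8
  solubility triplet (31/47/52 mg/mL, clamped outside that range). The
  fitted solubilization factor (616) is carried in `drug_params()` for
  reference but is not multiplied into the triplet, which is already a
  direct solubility measurement; at a 23 mg dose saturation never binds.
- **Absorption.** Per segment, absorptive flux is
  `ka = 2 Peff · scale / radius` times the dissolved amount, with
  Peff = 3.1×10⁻⁴ cm/s and documented segment radii and absorption
  scales (zero in the stomach, reduced in caecum/colon). The printed
  permeability is read as 3.1 in units of 10⁻⁴ cm/s.
- **Elimination.** A well-stirred liver with saturable CYP3A4 + CYP2D6
  Michaelis–Menten kinetics. Microsomal Vmax values (89 and
  125 ng/min/mg) scale to whole-liver capacity via MPPGL = 32 mg/g and
  1800 g liver; the CYP3A4 scale factor is 5.0 as reported. The CYP2D6
  scale factor is not published ("fitted"); this package's default of 6.0
  was calibrated once so the linear plasma clearance (~8.4 L/h) and
  terminal half-life (~66 h) match published donepezil disposition, and
  is never re-tuned. Extraction is evaluated at the liver **inlet**
  concentration (systemic blood plus absorbed gut flux diluted into
  hepatic blood flow, 90 L/h), so first-pass extraction saturates
  mechanistically when concentrations approach Km.
- **Disposition.** A lumped two-compartment model
  (`disposition_params()`: Vc = 6.5 L/kg, k12 = 0.025 h⁻¹,
  k21 = 0.035 h⁻¹, 70 kg) replaces full-body tissue-partition PBPK,
  which is out of scope. Its defaults were calibrated once against
  published donepezil behavior — immediate-release Tmax 3–5 h
  (simulated: 3.8 h), terminal half-life ~70 h (simulated: 66 h),
  Cmax ≈ 37 ng/mL at 23 mg — and left alone thereafter. Bioequivalence
  conclusions depend on relative test/reference behavior, which survives
  this substitution.

**Numerics.** `deSolve::lsoda` with rtol 1e-8/atol 1e-10; output grid
0.05 h by default (population simulations use 0.1 h — halving the grid
moves Cmax and AUC by <0.5%). Mass balance (all lumen species + central +
peripheral + eliminated + excreted = dose) is checked at every output
point; deviation beyond 0.1% of dose raises a simulation-integrity error.
The release hazard is capped at 500 h⁻¹ for numerical stability as the
release fraction approaches its plateau.

PK metrics are grid-based Cmax/Tmax, trapezoidal AUC0–t, and AUC0–∞ via
`Clast/λz` with λz from a log-linear fit over the last three post-peak
positive concentrations (missing, with a warning, when no negative
terminal slope exists). Model validation uses the average fold error,
$AFE = 10^{\frac1n\sum\log_{10}(pred_i/obs_i)}$, a pure bias metric
(over- and under-predictions cancel), satisfactory in [0.8, 1.25]. Since
the literature datasets behind the original validation are not shipped,
`make_clinical_dataset()` builds pseudo-observed studies by perturbing
permeability, metabolic capacity and gastric emptying and re-simulating;
the test suite asserts the AFE identities and that mild (±10%)
perturbations stay inside the band.

## 5. Parameter sensitivity analysis

`run_psa()` performs one-at-a-time multiplicative sweeps (default nine
log-spaced multipliers, 0.25×–4×, containing the exact baseline at 1×)
over an enumerated parameter set: Weibull lag, plateau, shapes and scales;
permeability; CYP3A4/CYP2D6 Vmax; and stomach transit time. Sensitivities
are normalized elasticities, d log(metric)/d log(parameter), from a
central difference at ±10% — unit-free by construction, so rankings are
comparable across parameters. One-at-a-time sweeps (not global
variance-based indices) match the single-parameter framing of the
analysis being reproduced; sweep ranges are package defaults and
configurable.

## 6. Virtual bioequivalence

Virtual populations draw log-normal, median-1 multipliers per parameter:
a between-subject (BSV) multiplier fixed across periods and an
independent within-subject (WSV) multiplier per period — the
"mechanistic intrasubject variability" approach, in which physiology and
formulation parameters are re-drawn per occasion rather than noise being
added to PK metrics. Default CVs are the tuned set: CYP3A4/CYP2D6 Vmax
15/15%, stomach transit 35/35%, Peff 30/30%, Weibull scales and shapes
5/5%, Fmax 3.2/3.2% (the latter rows representing in vitro dissolution
variability, applied to the administered formulation's Weibull parameters
each period like the physiological CVs). Populations are demographically
homogeneous (70 kg); demographic matching is out of scope.

Each trial is a two-sequence (TR/RT, balanced), two-period crossover.
Both metrics (Cmax, AUC0–t) are analysed on the log scale with the
classical fixed-effects crossover model (treatment + period + subject);
the GMR is `exp` of the treatment effect and the 90% CI uses the
within-subject residual variance on n−2 degrees of freedom — the standard
TOST-equivalent analysis. A trial passes when both CIs lie inside
80–125%. `run_vbe_study()` repeats 15 independent trials (seed-derived
population streams) and maps pass counts to risk tiers: low ≥13/15,
moderate 9–12, high <9 (proportional cuts for other trial counts).
`sample_size_step()` steps the population size upward under common random
numbers until the empirical power (fraction of passing trials) reaches
80%.

**AUC window.** BE metrics use AUC0–72 h from a single-dose simulation —
the standard truncated-AUC practice for long-half-life drugs — on a 0.1 h
grid; the headline study (15 trials × 24 subjects × 2 periods) runs in a
few minutes on one CPU.

## 7. Synthetic data: what it does and does not show

`make_bbd_dataset()`, `make_dissolution_dataset()` and
`make_clinical_dataset()` generate every fixture the pipeline needs, as
pure functions of a seed: design responses from known quadratic surfaces
plus Gaussian noise (default truth = the published retained-coefficient
sets, σ = 1 percentage point); multi-vessel dissolution profiles sampled
from Weibull truth curves at the 0.5/1/2.5/5/13 h schedule with truncated
Gaussian noise, clipped to [0, 100] and made monotone per vessel; and
perturbation-based pseudo-clinical studies. These emulate the *structure*
of real screening and validation data — replicate noise, vessel-to-vessel
scatter, study-to-study parameter shifts. They do not emulate assay bias,
non-Gaussian outliers, correlated vessel effects, or real between-study
heterogeneity in demographics and formulations; passing tests therefore
demonstrate correct recovery and calibrated inference under the stated
noise model, not validation against clinical data — which is exactly the
boundary the synthetic stand-ins are documented to have.

## 8. Known limitations

- The disposition model is a calibrated lumped two-compartment
  substitute; absolute exposures are plausible rather than validated, and
  conclusions should be read as relative (test vs reference).
- First-pass saturation uses the liver-inlet approximation of the
  well-stirred model; at therapeutic donepezil doses the model operates
  far below Km, so this matters only in deliberate stress tests.
- The release hazard formulation assumes the dosage form distributes with
  the luminal contents (first-order transit of the unreleased depot);
  monolithic-tablet position is not tracked discretely.
- No fed-state physiology, transporters, enterohepatic recycling, or
  replicate/scaled BE designs.

## Problem sizes used by the shipped checks

The package's own test suite runs the headline virtual-bioequivalence
study at its full size (15 trials × 24 subjects × 2 periods) and all other
simulation-based properties on a 48 h window with a 0.2 h grid; Monte
Carlo calibration of the term-retention rate uses 200 replicated designs.
These sizes were chosen so the whole suite exercises every stage at
meaningful fidelity in a few minutes on a single CPU.
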