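Package: formsim
Title: Formulation Optimization and Virtual Bioequivalence for
    Extended-Release Oral Dosage Forms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated workflow for model-informed development of
    extended-release hydrophilic matrix tablets, using donepezil as the
    worked system. Provides Box-Behnken response-surface design and
    quadratic modeling of release responses with composition optimization
    against a target dissolution profile; single and double Weibull
    dissolution kinetics with f2 similarity testing (including vessel
    bootstrap); tablet hydration, erosion and gel-strength metrics; a
    compartmental gastrointestinal transit and absorption (ACAT-style)
    simulator with saturable CYP3A4/CYP2D6 elimination and two-compartment
    disposition; average-fold-error model validation; one-at-a-time
    parameter sensitivity analysis; and mechanistic virtual bioequivalence
    trials (two-sequence, two-period crossover) with risk categorization.
    Synthetic-data generators emulate the design tables, multi-vessel
    dissolution profiles and pseudo-observed clinical datasets needed to
    exercise every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
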