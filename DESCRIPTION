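Package: nmephys
Title: Boltzmann Modeling of Potassium Conductances and Intrinsic Properties
    of Cochlear-Nucleus Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell patch-clamp recordings from
    developing avian cochlear-nucleus (nucleus magnocellularis) neurons.
    Extracts steady-state potassium currents from voltage-clamp sweep
    families, builds junction-corrected I-V curves, models low- and
    high-voltage-activated potassium conductances with Boltzmann activation
    curves (open probability, differential conductance, and the integrated
    closed-form I-V), extracts action-potential and passive membrane
    properties from current-clamp sweeps, applies inclusion and outlier
    rules, and runs the group-comparison statistics battery (Welch t,
    ANOVA with Bonferroni comparisons, Brown-Forsythe and Welch ANOVAs).
    Includes a single-compartment conductance-model generator that
    simulates control and BDNF-treated cohorts with known ground-truth
    channel parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
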