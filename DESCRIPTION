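Package: fscvr
Title: Phasic Dopamine Transient Analysis for Fast-Scan Cyclic Voltammetry
    with Opioid Dose-Response and Plasma Pharmacokinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing sub-second dopamine release ("transients")
    recorded with in vivo fast-scan cyclic voltammetry (FSCV) during
    cumulative intravenous opioid dosing. Includes chemometric extraction of
    dopamine from raw voltammogram streams (background subtraction,
    principal-component regression against labelled training sets, molar
    calibration), per-minute transient detection by dual polynomial fitting
    with AIC-guided degree selection and a refractory peak-merging rule,
    epoch-wise dose-response summaries with allometric human-to-rat dose
    conversion, a normality/variance-gated parametric-vs-nonparametric
    comparison procedure, LC-MS standard-curve plasma quantification, and a
    seeded synthetic-session generator (Poisson transient trains, drifting
    baselines, forward voltammetric model, one-compartment plasma kinetics)
    so that every stage of the pipeline can be validated against known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    car,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
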