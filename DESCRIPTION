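Package: vancopk
Title: Population Pharmacokinetics and AUC-Guided Dosing of Vancomycin in
    Adults of Advanced Age
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects analysis of vancomycin concentration
    data in patients aged 75 years and older. Implements an analytic
    two-compartment intravenous-infusion model, FOCE-I (first-order
    conditional estimation with interaction) population fitting with
    stepwise covariate selection, bootstrap and standard diagnostics
    (empirical Bayes estimates, eta-shrinkage, conditional weighted
    residuals, visual predictive checks), MAP Bayesian individual
    clearance estimation from sparse peak/trough sampling, predictive
    performance metrics against reference clearances, and a Monte-Carlo
    probability-of-target-attainment engine that builds an AUC-guided
    creatinine-clearance by serum-albumin dosing nomogram. A synthetic
    cohort generator reproduces the statistical structure of the modeled
    elderly population so the full pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
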