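Package: vancopk
Title: Population Pharmacokinetics of Vancomycin in Infants Stratified by Renal Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-compartment intravenous-infusion population pharmacokinetic
    modelling of vancomycin in infants, with renal-function-stratified covariate
    models (normal renal function versus augmented renal clearance, split by
    Schwartz estimated glomerular filtration rate). Provides closed-form
    multi-infusion concentration prediction, a from-scratch first-order
    conditional estimation (FOCE with interaction, Laplace form) engine for
    nonlinear mixed-effects models with log-normal between-subject variability,
    allometric and maturation covariate structures, stepwise forward-addition /
    backward-elimination covariate selection, and a diagnostic suite: empirical
    Bayes estimates and shrinkage, conditional weighted residuals, visual
    predictive checks, nonparametric bootstrap, and external-validation
    prediction-error metrics with paired model comparison. A synthetic-cohort
    generator reproduces the therapeutic-drug-monitoring study design
    (weight-based dosing split into 2-4 daily infusions, trough and peak
    sampling around the fifth dose) for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    pracma,
    stats,
    graphics,
    grDevices,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
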