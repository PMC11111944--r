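Package: tacppk
Title: Population Pharmacokinetics and PK-Informed Machine Learning for
    Tacrolimus Trough Concentrations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two-stage prediction of tacrolimus trough concentrations in
    renal transplant recipients.  Stage one is a nonlinear mixed-effects
    population-pharmacokinetic model (one-compartment, first-order
    absorption, log-additive residual) estimated by first-order
    conditional (Laplace-at-the-mode) approximation of the marginal
    likelihood, with stepwise likelihood-ratio covariate selection on
    apparent clearance, empirical-Bayes (MAP) forecasting, conditional
    weighted residuals and visual predictive checks.  Stage two feeds the
    individual predictions of the covariate-free model, dosing-history
    features and clinical covariates into machine-learning regressors
    (gradient-boosted trees, RBF support-vector regression, feed-forward
    network) tuned by a Tree-structured Parzen Estimator under nested,
    patient-grouped cross-validation, with exact Shapley attribution for
    tree ensembles.  A synthetic-cohort generator reproduces the design of
    a titrated twice-daily dosing protocol so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    xgboost,
    e1071,
    nnet
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    pracma
Config/testthat/edition: 3
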