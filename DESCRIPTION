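Package: abcreg
Title: Abundance-Based Constraints for Regression with Categorical
    Effect Modifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identified, equitable estimation and inference for linear
    regression models in which continuous covariate effects are modified
    by categorical covariates (race, sex, education level, and similar
    group structure). Identification uses abundance-based constraints
    (ABCs), which weight each categorical level's coefficients by the
    group proportions so that main effects are group-averaged effects and
    level effects are deviations from the average. Fitting is linearly
    constrained least squares via an orthonormal null-space
    reparametrization, with exact finite-sample inference, adaptive ridge
    and lasso regularization on the constrained parametrization,
    moment-based invariance diagnostics, and simulation tools that
    compare ABCs with reference-group, sum-to-zero, and overparametrized
    identification schemes.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
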