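Package: tdm1popk
Title: Population Pharmacokinetic Analysis of Trastuzumab Emtansine (T-DM1)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reproduce and exercise a population pharmacokinetic
    analysis of the antibody-drug conjugate trastuzumab emtansine (T-DM1):
    a linear two-compartment disposition model with a six-covariate model on
    clearance and central volume, closed-form concentration prediction and
    steady-state exposure metrics, simulation of virtual trials with
    proportional residual error and below-quantification censoring,
    nonlinear mixed-effects estimation (FOCE with interaction) with
    empirical-Bayes individual estimation and stepwise covariate selection,
    and the validation machinery used in population PK practice (prediction
    errors, visual and numerical predictive checks, bootstrap, shrinkage),
    plus covariate sensitivity and subgroup exposure analyses. All analyses
    run on synthetic cohorts generated by the package itself.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
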