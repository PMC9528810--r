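Package: snarml
Title: Hybrid Mechanistic/Machine-Learning Prediction of SNAr Activation
    Free Energies
Version: 0.1.0
Authors@R:
    person("Kinetics", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting experimental activation free energies of
    nucleophilic aromatic substitution (SNAr) reactions with hybrid models
    that combine DFT-derived transition-state descriptors and ground-state
    physical-organic features. Provides Eyring interconversion of rate
    constants and barriers, named feature-set assembly with polynomial
    expansion and Morgan reaction difference fingerprints, a model zoo
    (linear, ARD, random forest, support-vector and Matern-3/2 Gaussian
    process regression) with predictive uncertainty, bootstrap
    bias-corrected cross-validation for honest model selection, learning
    curves and grouped validation, multicollinearity-aware feature
    importance, applicability-domain diagnostics (PLS DModX, accuracy
    averaging curves, interval coverage), barrier-based regio- and
    chemoselectivity prediction, and a synthetic-data generator emulating
    the statistical structure of kinetic datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
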