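Package: fdantcp
Title: Functional Data Analysis for Normal Tissue Complication Probability
    Modeling of Dose-Volume Histograms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dimensionality reduction of fractional-dose dose-volume
    histogram (DVH) curves by functional principal component analysis (FPCA)
    and functional partial least squares (FPLS), functional logistic
    regression of binary radiotherapy toxicity outcomes with clinical
    covariates and a curvature (roughness) penalty, BIC-style model selection
    over component count and penalty strength, a LASSO-penalized logistic
    regression comparator on discrete DVH points, and an internal-validation
    suite (bootstrap optimism-corrected AUC, Brier score and calibration
    slope/intercept, plus percentile bootstrap odds-ratio confidence
    intervals). Includes a synthetic DVH cohort generator with a known
    dose-weighting function for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
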