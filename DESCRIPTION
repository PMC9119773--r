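Package: riskdistill
Title: Transparent Additive Risk Scores from Supervised Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distills opaque supervised classifiers into transparent additive
    risk scores. Candidate learners (logistic regression, single-hidden-layer
    neural networks, linear and radial-kernel support vector machines, tree
    ensembles) are trained and benchmarked under stratified cross-validation;
    relative feature weights are extracted from the winning models via
    connection-weight (Garson/Olden) analysis, hyperplane coordinates,
    impurity importances, or recursive feature elimination; the weights form
    a 0-100 prognostic index that is refit as a one-covariate logistic risk
    equation and validated with Brier score, Spiegelhalter's Z, the
    Hosmer-Lemeshow H statistic, calibration tables, and AUC. Includes a
    seeded generator for matched case-control cohorts of binary risk-factor
    indicators with known ground-truth feature effects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    e1071,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
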