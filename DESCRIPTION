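Package: moderanet
Title: Prognostic and Prescriptive Predictor Discovery with Repeated
    Elastic-Net Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying baseline predictors of post-treatment
    depression severity in two-arm randomized trials, distinguishing prognostic
    effects from prescriptive (treatment-moderating) group interactions.
    Includes trial-level scoring of conflict-task (Flanker) behavior
    (interference, congruency-sequence and post-error adjustment effects),
    Fisher-z resting-state connectivity features from ROI time series,
    iterative random-forest imputation, repeated elastic-net stability
    selection with cross-validated penalty tuning, nested cross-validated
    model comparison with variance-corrected t-tests, and a final
    interpretive linear model with adjusted-effect curves. A synthetic-cohort
    generator with plantable prognostic and interaction effects supports
    calibration and power checks without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    randomForest,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
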