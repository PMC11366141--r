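Package: icumotion
Title: Accelerometer Movement Biomarkers and Penalized Mixed-Model
    Prediction of Muscle Atrophy in Critical Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving movement biomarkers from thigh-fixed
    tri-axial accelerometer recordings of critically ill patients
    (signal magnitude area over 5 s windows, activity-bout detection at
    the 0.135 g threshold, log-normal bout features, proportion of
    active movement) and for predicting rectus femoris muscle atrophy
    from them with an L1-penalized linear mixed model (patient random
    intercepts, GLS-whitened coordinate descent with soft-thresholding),
    tuned by nested cross-validation and accompanied by cluster
    bias-corrected and accelerated (BCa) bootstrap confidence intervals,
    variance-inflation-factor pruning, grouped stratified splitting,
    Gaussian generalized estimating equations for limb-group contrasts,
    and a synthetic-data generator that emulates a neurocritical care
    cohort with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    lme4,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
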