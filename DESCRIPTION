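Package: usradiomics
Title: Ultrasound Texture Radiomics for Breast Lesion Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Radiomics analysis of grayscale breast ultrasound images for
    discriminating triple-negative breast cancer from fibroadenoma. Extracts
    a named 730-feature texture signature per lesion (14 intensity-based
    features, 132 gray-level co-occurrence and run-length features over four
    directions, and 584 coiflet wavelet subband features), builds a sparse
    radiomics score by LASSO-penalized logistic regression with
    cross-validated tuning that maximizes the area under the ROC curve, and
    converts scores to predicted malignancy probabilities through a logistic
    calibration. Includes a seeded speckle-image simulator for generating
    synthetic lesion cohorts with class-dependent texture and
    machine-dependent brightness effects, interobserver agreement analysis
    via two-way random-effects intraclass correlation, and reporting
    utilities for split balance, per-machine score comparison, and subgroup
    performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC,
    tiff
Config/testthat/edition: 3
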