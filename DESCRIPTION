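Package: habitomics
Title: Multi-Habitat MRI Radiomics for Treatment-Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for habitat-based MRI radiomics: 3D radiomic
    feature extraction (shape, histogram, gray-level co-occurrence and
    run-length texture families, on original and Haar wavelet sub-band
    images) from tumor habitats delineated on co-registered MRI sequences;
    three-step feature selection (ICC stability, pairwise-correlation
    redundancy pruning, LASSO logistic regression) into per-habitat
    signatures; grid-searched fusion of signatures and clinical covariates
    into a single response-prediction model (logistic regression, SVM, or
    random forest); and a full evaluation battery (ROC/AUC with DeLong
    confidence intervals and tests, Youden cutoff, Hosmer-Lemeshow
    calibration, inter-radiologist consistency ICC, repeated random-split
    validation). Includes a NIfTI-backed synthetic cohort generator with
    planted texture effects so the whole chain is testable without access
    to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    glmnet,
    pROC,
    e1071,
    randomForest,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
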