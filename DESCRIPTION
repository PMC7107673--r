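Package: strokehier
Title: Hierarchical Machine-Learning Triage of Large Vessel Occlusion Stroke
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic implementation of a three-tier
    evaluation system for large vessel occlusion (LVO) in acute ischemic
    stroke. The package generates tabular patient cohorts and pseudo-CT head
    phantoms carrying the hyperdense middle-cerebral-artery (MCA) sign,
    preprocesses non-contrast CT volumes into hemispheric regions of interest,
    trains an encoder-decoder fully convolutional network with Tversky loss
    and hard-negative mining to segment the MCA sign, reuses it as a
    global-max-pool deep feature extractor, and fits four tabular learners
    (stepwise logistic regression, random forest, SVM, gradient boosting)
    over three nested feature levels with KNN-median imputation and
    Youden-index cutoff selection via 10-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    RNifti,
    randomForest,
    e1071,
    xgboost,
    glmnet,
    pROC,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
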