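Package: cmbkit
Title: Patch-Based 3D CNN Toolkit for Cerebral Microbleed Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for recognising cerebral microbleeds (CMBs) in
    susceptibility-sensitive brain MRI. Provides a synthetic phantom
    generator with hypointense spheroidal lesions and CMB mimics, NIfTI
    volume input/output with RAS/voxel coordinate conversion, labelled
    3D patch extraction with class-imbalance handling (undersampling and
    four training-set assembly strategies), a small 3D convolutional
    network trained from scratch with Adam and cross-entropy, blob-based
    candidate proposal with hard-negative (false-positive) mining, and an
    evaluation kit with balanced accuracy, precision, sensitivity,
    F1-score, AUC, burden-stratified reporting and repeated stratified
    k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
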