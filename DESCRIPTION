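Package: scintimet
Title: Supervised Contrastive Learning for Bone-Metastasis Detection on
    Whole-Body Bone Scintigraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for binary classification of whole-body planar
    bone scans (anterior/posterior pairs) into metastasis-present versus
    metastasis-absent. Provides a synthetic scintigraphy phantom generator
    with Poisson counting noise and benign confounders, a minimal planar-NM
    DICOM reader/writer, the view-merging and thigh-ROI normalization
    preprocessing chain, a small convolutional encoder with a supervised
    contrastive (SupCon) training phase followed by a linear probe, a plain
    supervised baseline, stratified k-fold splitting, NPV-centric
    confusion-matrix metrics with ROC/AUC, and UMAP-based embedding
    inspection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    cluster,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
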