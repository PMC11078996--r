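Package: oomorph
Title: Morphometric Oocyte Assessment with Interpretable Outcome Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale workflow for interpretable assessment of denuded
    metaphase-II oocytes from two-dimensional micrographs. Provides a
    synthetic oocyte phantom generator with analytic ground truth, a
    classical multi-class baseline segmenter with per-class intersection
    over union evaluation, sub-pixel morphometry of the ooplasm,
    perivitelline space and zona pellucida (aspect ratio, circularity,
    roundness, solidity and between-region ratio features), cohort-relative
    feature engineering, patient-level data splitting, gradient-boosted
    outcome classification, ROC/AUC evaluation with paired DeLong tests,
    feature-group ablations and subgroup analysis, and exact interventional
    Shapley-value explanations of individual predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    Rcpp,
    xgboost,
    data.table,
    EBImage,
    png,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: CellBiology, FeatureExtraction, Classification, Segmentation
RoxygenNote: 7.3.3
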