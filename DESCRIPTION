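Package: hyperobia
Title: Object-Based Multi-Feature Classification of Hyperspectral Vegetation Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An object-based image analysis (OBIA) pipeline for classifying
    vegetation species in hyperspectral imagery, developed around mangrove
    mapping from UAV-acquired reflectance cubes. Provides Grünwald-Letnikov
    fractional-order spectral differentiation, a catalogue of 15 hyperspectral
    vegetation indices, sliding-window grey-level co-occurrence matrix (GLCM)
    texture statistics on principal-component images with Jeffries-Matusita
    separability-driven window selection, region-based segmentation with
    per-object feature aggregation and 14 geometric descriptors, genetic-
    algorithm wrapper feature selection, four classical classifiers (KNN, SVM,
    random forest, single-hidden-layer neural network) with confusion-matrix
    accuracy assessment (overall accuracy, average accuracy, Cohen's kappa),
    and a labelled synthetic-scene simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    tiff,
    e1071,
    randomForest,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
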