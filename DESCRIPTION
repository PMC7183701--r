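Package: lnradiomics
Title: Radiomic Texture Analysis for Preoperative Lymph-Node Metastasis
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying lymph nodes as normal or
    metastatic from single-slice CT regions of interest. Implements a
    146-feature texture panel (first-order statistics, gray-level
    co-occurrence and run-length matrices, local binary patterns, fractal
    dimension, shape descriptors, and wavelet- and gradient-domain
    variants), LASSO-based feature selection with cross-validation,
    kernel support-vector-machine classifiers, and DeLong-based ROC
    comparison against the clinical 10 mm size-threshold rule. A
    synthetic lymph-node cohort generator with class-dependent size and
    texture structure makes the whole analysis testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    glmnet,
    e1071,
    jsonlite,
    RNifti,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
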