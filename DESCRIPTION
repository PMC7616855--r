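Package: erfscope
Title: Effective-Receptive-Field Probing of Convolutional Image Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates families of bottleneck residual convolutional classifiers whose
    theoretical effective receptive field (ERF) is controlled through the middle filter
    sizes of their residual units, and probes how such networks use the spatial
    arrangement of features for object recognition. Provides analytic receptive-field
    arithmetic with an empirical gradient-support cross-check, a compact CPU training
    engine (convolution, batch normalization, SGD with momentum), spatial feature
    scrambling with frozen-base/follow-up model composition, per-class scrambling
    sensitivity statistics, representational similarity analysis (first- and
    second-order dissimilarity matrices, multidimensional scaling), a recursive
    minimal-recognizable-configuration (MIRC) patch search, and seeded synthetic image
    datasets whose class identity is carried either by local texture statistics or
    solely by the spatial arrangement of a shared part inventory.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    png,
    EBImage
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
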