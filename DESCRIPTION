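Package: tubuleseg
Title: Patch-Based Tubule Segmentation for Breast Histopathology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A patch-based semantic segmentation framework for tubule
    structures in haematoxylin-and-eosin stained breast tissue images.
    Provides reflection and mirror patch-enhancement padding, overlap
    tiling and stitching for images larger than one patch, symmetric and
    asymmetric (classification-backbone encoder) U-Net segmentation
    models built on a compact CPU convolutional-network engine, a
    training loop with Adam, step learning-rate decay and early stopping,
    pixel-level Dice/recall/specificity evaluation with overlay
    rendering, and a seeded synthetic tubule-phantom generator with
    pixel-perfect ground truth for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
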