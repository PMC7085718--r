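Package: semreg
Title: Semantically Guided Two-Step Deformable Image Registration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Weakly supervised deformable registration of 2D greyscale images
    with large initial misalignment. A compact U-Net extracts per-pixel class
    probabilities (semantic features) under a weighted cross-entropy loss; two
    cascaded convolutional registration networks predict coarse B-spline
    control-grid displacements that are densified by repeated average pooling
    (the recursive cardinal-spline construction) and combined into a single
    dense deformation field. Training is end-to-end from segmentation overlap,
    semantic, and smoothness losses; no ground-truth correspondence fields are
    needed. Includes a diffeomorphic variant via stationary velocity fields and
    scaling-and-squaring, evaluation metrics (Dice, symmetric contour distance,
    Jacobian-determinant summaries), and a synthetic-scene generator with known
    ground-truth deformations for testing and benchmarking.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    png,
    utils,
    stats
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
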