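Package: rfcnet
Title: Recurrent Fully Convolutional Networks for Joint Optic Disc and Cup Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint segmentation of the optic disc and optic cup in fundus
    photographs with a recurrent fully convolutional network (RFC-Net).
    Provides the polar-coordinate preprocessing that rebalances the small
    optic-cup class, recurrent convolutional layers with weight sharing
    across unfolding steps, a multi-scale input pyramid with deeply
    supervised multi-output heads, the weighted multi-output cross-entropy
    loss, boundary-localization-error and pixel-overlap evaluation metrics,
    a seeded synthetic fundus generator for testing, and a training /
    prediction / evaluation pipeline with a command-line interface. The
    network forward and backward passes are implemented from scratch in
    C++ (im2col plus BLAS matrix products).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
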