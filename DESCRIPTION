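Package: mscnet
Title: Multi-Task Vessel Segmentation and Artery/Vein Classification for
    Retinal Fundus Images
Version: 0.1.0
Authors@R: person("mscnet", "developers", role = c("aut", "cre"),
    email = "mscnet@example.org")
Description: Pixel-level artery/vein classification in retinal fundus
    photographs via a three-stage network: multi-scale vessel extraction
    with split-concat residual blocks, contextual-attention artery/vein
    extraction, and multi-source feature fusion driven by a vessel
    enhancement activation. Ships a seeded synthetic fundus generator,
    CLAHE-based preprocessing, patch training with a composite Dice and
    cross-entropy objective, tiled inference, evaluation metrics, and a
    command-line interface. Training runs on a small built-in
    reverse-mode autodiff engine with compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    jpeg,
    optparse,
    stats,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
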