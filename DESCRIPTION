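Package: tomseg
Title: Two-Stage RGB-D Semantic Segmentation for Tomato Sucker Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of tomato suckers (axillary shoots) in RGB-D images by a
    lightweight two-stage cascade semantic-segmentation network. Provides a
    lossless 24-bit PNG depth codec, a seeded synthetic tomato-scene generator,
    depthwise-separable convolution building blocks with exact trainable
    parameter accounting, hard-pixel cascade gating with selective depth
    fusion, a two-phase training protocol, and class-IOU plus
    connected-component sucker-counting evaluation. The network layers
    (grouped/dilated convolution, batch normalization, bilinear resampling,
    pyramid pooling) ship with their own forward and backward passes so the
    whole pipeline runs on a plain CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
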