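Package: leukoseg
Title: Residual Attention Encoder-Decoder Segmentation of White Blood Cell Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Semantic segmentation of single white blood cell (leukocyte)
    microscopy images with a U-Net-style encoder-decoder network: a
    ResNet50-style bottleneck residual encoder, a decoder with
    squeeze-and-excitation channel attention and atrous (dilated)
    convolutions, bilinear upsampling and skip connections. Ships binary
    cross-entropy and focal losses, Dice/mIoU/PPV/sensitivity/Hausdorff
    evaluation, morphological mask cleanup, a synthetic single-cell image
    generator emulating the difficulty of stained blood smears (cytoplasm
    color close to the background, uneven brightness, irregular
    boundaries), and seeded training with Adam. All tensor operations are
    implemented in the package with Rcpp/RcppArmadillo compute kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
biocViews: ImageSegmentation, CellBiology, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
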