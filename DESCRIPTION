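Package: lmsaunet
Title: Lightweight Multi-Scale Attention U-Net for Skin Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: A lightweight encoder-decoder segmentation network for dermoscopy
    images, built around an efficient channel-compressed dual-branch depthwise
    feature block (ECDF) with parallel spatial-channel attention, a joint
    binary cross-entropy plus soft-IoU training objective, pixel-confusion
    evaluation metrics (accuracy, IoU, Dice, frequency-weighted IoU), a
    parameter and multiply-accumulate auditor, and a seeded generator of
    synthetic dermoscopy-like image/mask pairs so the whole system trains and
    tests at desk scale on the CPU without any dataset download. Forward and
    backward passes are implemented in R with compiled kernels for the
    depthwise and pooling loops.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    png,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo:
    RcppArmadillo,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
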