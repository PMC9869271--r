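Package: glandnet
Title: Segmentation and Counting of Pigment Glands in Cotton Leaf Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and counts cotton pigment glands in RGB leaf images
    with an interpolation-first, pooling-second encoder-decoder
    segmentation network trained on mean squared error against binary
    gland masks. Provides tile-based inference with margin-trimmed
    stitching for large images, connected-domain counting with
    shape-feature (area) post-filtering and morphological closing,
    confusion-matrix segmentation metrics (mIoU, precision, recall, F1)
    and counting agreement statistics, a synthetic leaf-scene generator
    with known ground truth at three gland density levels, LabelMe-style
    polygon annotation rasterization, and a command-line pipeline for
    generating data, training, predicting, counting and evaluating.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
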