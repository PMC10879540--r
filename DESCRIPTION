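Package: ercpnet
Title: Channel-Expansion Residual Networks with Adaptive Channel Attention for Leaf Disease Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds, trains and interprets compact convolutional networks for
    multi-class plant leaf disease classification. Provides the channel-expansion
    residual block (CER), which triples channel width through parameter-free
    multi-window max pooling; an adaptive channel attention block (ACA) whose 1D
    convolution kernel size is derived from the channel count through the inverse
    Gaussian probability density function; a bidirectional information fusion head
    (BIF); a CBAM baseline for ablations; a deterministic synthetic leaf-image
    generator; an SGD training harness with plateau learning-rate decay; confusion
    matrix and macro precision/recall metrics; and Grad-CAM heatmaps. All tensor
    operations (convolution, batch normalisation, pooling) and their gradients are
    implemented in base R, so the package is fully self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
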