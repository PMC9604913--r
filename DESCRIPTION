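Package: siftcnn
Title: SIFT Images as Inputs for Convolutional Classifiers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Transforms single-channel images into dense per-pixel SIFT
    descriptor images (one 128-dimensional gradient-orientation histogram per
    pixel, preserving spatial size) and trains convolutional classifiers on
    them. Implements the SIFT-image representation with exact channel
    permutation equivariances under quarter-turn rotation and horizontal flip,
    a compact CNN engine (residual backbones, channel-reduction stem for frame
    sequences, late pixel+SIFT feature fusion, SVM on fused features), step
    learning-rate training recipes with transfer learning, and a deterministic
    synthetic oriented-texture benchmark in which class identity is carried by
    local gradient-orientation statistics under random local rotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    png,
    tiff,
    withr,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse
Config/testthat/edition: 3
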