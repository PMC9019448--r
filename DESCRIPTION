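Package: vestibuleseg
Title: Hybrid 2D/3D Convolutional Segmentation of the Vestibule in CT Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of the inner-ear vestibule, a tiny low-contrast structure,
    from temporal-bone CT volumes using a hybrid deep network: an intraslice 2D
    encoder-decoder with multi-receptive-field convolution fusion and
    squeeze-and-excitation channel attention, an interslice 3D DenseUNet
    (DenseNet-BC encoder, growth rate 32, half-depth dense blocks), and a hybrid
    feature-fusion head combining the two feature streams into per-voxel class
    scores. Includes a synthetic CT phantom generator for testing at desk scale,
    Hounsfield windowing and patch utilities, a two-stage training procedure with
    class-weighted cross-entropy, ablation modes, and spacing-aware evaluation
    metrics (Dice coefficient, average symmetric surface distance, average
    Hausdorff distance). Convolution, pooling and batch-normalisation primitives
    with reverse-mode automatic differentiation are implemented in the package
    (Rcpp/RcppArmadillo), so no external deep-learning runtime is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
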