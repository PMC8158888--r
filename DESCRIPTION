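Package: pancseg
Title: Coarse-to-Fine 2.5D Attention U-Net for Small-Organ Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segmentation of small, low-contrast organs (such as the pancreas)
    from 3D grayscale volumes using a 2.5D U-like encoder-decoder with dense
    convolution blocks and a hybrid spatial/channel attention module on the
    skip connections, arranged in a coarse-to-fine multi-view cascade: three
    per-view models (sagittal, coronal, axial) are fused by per-voxel majority
    vote, the fused coarse mask defines a framed crop, and a second set of
    models segments the crop at higher effective resolution. Includes NIfTI
    volume I/O with Hounsfield windowing and resizing, Dice metrics and Dice
    loss, a seeded phantom-volume generator for end-to-end testing without
    external data, a CPU training harness (Adam, slice filtering, k-fold
    cross-validation), and a command-line interface. The network runtime is a
    self-contained reverse-mode autodifferentiation tape over Rcpp/Armadillo
    convolution, pooling and resampling kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
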