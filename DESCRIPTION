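Package: adverseg
Title: Adversarial Semantic Segmentation of Hippocampal Subfields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slice-based multi-class segmentation of hippocampal subfields in
    brain MR volumes with a generative adversarial pair: a single-convolution
    U-net variant (UG-net) producing per-pixel class probability maps, trained
    against a convolutional adversary under a hybrid multi-class/binary
    cross-entropy objective with alternating SGD-momentum updates. Includes a
    synthetic multi-subfield phantom generator emulating the layout of
    ROI-cropped subfield datasets (112x103x24 voxel volumes, 24 axial slices,
    9 subfield classes plus background), slice augmentation by rotation,
    translation and Gaussian noise, volume-level Dice similarity coefficient
    evaluation, and subject-level k-fold cross-validation.
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
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
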