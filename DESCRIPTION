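Package: dwiseg
Title: Two-Stage Convolutional Cascade for Acute Ischemic Lesion
    Segmentation in Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fully automatic segmentation of acute ischemic stroke lesions
    in diffusion-weighted MR images (DWI) using a two-stage convolutional
    cascade. Stage one is an ensemble of encoder-decoder networks with
    pooling-mask unpooling that produces a per-pixel lesion probability
    map; stage two evaluates small candidate components with a multi-scale
    patch classifier and removes false positives by Bayesian fusion of
    instance- and pixel-level evidence. The package includes NIfTI
    preprocessing (in-plane resampling, intensity normalisation),
    lesion-pixel patch sampling with augmentation, component-level
    evaluation metrics (Dice, false-positive/false-negative component
    counts and sizes, subject detection rate) with small/large lesion
    stratification, and a synthetic phantom generator so the whole
    pipeline is trainable and testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
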