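Package: ratbex
Title: Rodent Brain Extraction from Volumetric MRI with a 3D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automatic skull stripping (brain extraction) for rodent MRI
    volumes using an encoder-decoder convolutional network (U-Net) with
    2D or 3D convolutions. Provides NIfTI volume input/output with
    nearest-neighbour resampling and intensity normalisation, a
    configurable U-Net implemented natively in R and C++ (Dice-loss
    patch training with Adam and gradient-norm clipping), overlapped
    sliding-window inference with probability averaging, a synthetic
    rodent-head phantom generator for fully offline testing, the
    standard segmentation evaluation metrics (Dice, Jaccard, positive
    predictive value, sensitivity, centre-of-mass distance, slice-wise
    Hausdorff distance) and a volume-of-interest based signal-to-noise
    estimator, plus robustness harnesses sweeping additive Gaussian
    noise and training sample size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
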