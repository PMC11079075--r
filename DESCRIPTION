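Package: cbctools
Title: Adaptive Histogram-Based Preprocessing and Evaluation Tools for
    Dental CBCT Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Cone beam computed tomography (CBCT) gray values are not
    calibrated across devices, so fixed-percentile intensity windows fail
    to standardize scans from different manufacturers. 'cbctools'
    implements an adaptive preprocessing method that models the dominant
    soft-tissue mode of the gray-value histogram with a Gaussian and
    derives a bone truncation threshold from the fitted peak, together
    with the surrounding apparatus for deep-learning segmentation
    pipelines: isotropic resampling and z-normalization, volumetric
    training augmentations (random crop, mirror flip, cutout masks), a
    combined cross-entropy plus soft Dice loss, a 3D segmentation metric
    suite (Dice, mIoU, Hausdorff distance, average surface distance) with
    FDI two-digit tooth-position reporting, and a synthetic dental CT
    phantom generator with exact ground-truth labels for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
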