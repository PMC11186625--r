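Package: photorecon
Title: 3D Reconstruction and Analysis of Dissection Photographs of Brain Slices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns 2D dissection photographs of coronal brain slices into
    calibrated, 3D-reconstructed volumes. Provides fiducial-based perspective
    correction and pixel-size calibration, tissue segmentation and slice
    grouping, joint slice-to-volume registration against a surface-scan or
    probabilistic-atlas reference by maximizing a soft-Dice/normalized
    cross-correlation objective with L-BFGS, a domain-randomized synthetic
    image generator for label-conditioned training data, a digital slicing
    simulator with thickness jitter for quantifying reconstruction error, and
    the evaluation statistics used in ex vivo volumetry studies (2D Dice,
    AUROC, Wilcoxon rank-sum, GLM covariate correction, Steiger tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    RNifti,
    jsonlite,
    png,
    tibble,
    generics,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
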