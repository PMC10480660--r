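Package: hdpaint
Title: High-Density PAINT Super-Resolution Reconstruction with a
    Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Accelerated single-molecule localization microscopy (SMLM) for
    PAINT data recorded with exchangeable protein labels. Provides a
    binding-kinetics PAINT simulator with an EMCCD camera model and exact
    ground truth; integrated-Gaussian maximum-likelihood spot fitting with
    Mortensen precision estimates, NeNA precision analysis, localization
    linking and redundant cross-correlation drift correction; synthesis of
    high-density training patches by summing low-density acquisitions; a
    DeepSTORM-style convolutional encoder-decoder (implemented natively)
    that predicts upsampled localization-density maps from high-density
    frames, with count-calibrated thresholding and centroid extraction;
    image-quality assessment (PCC, SSIM, MS-SSIM, MAE, PSNR and
    decorrelation-analysis resolution); and sliding-window super-resolution
    movie generation for live-cell dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    tiff,
    png,
    yaml,
    jsonlite,
    stats,
    graphics,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
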