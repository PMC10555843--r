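Package: blindspot
Title: Self-Supervised Blind-Spot Denoising for Voltage Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Self-supervised removal of Poisson-Gaussian noise from
    voltage imaging movies. A convolutional network predicts every pixel of
    the current frame from its spatiotemporal neighbours while a structural
    blind spot guarantees that the pixel's own noisy value never enters its
    prediction, so the noisy movie itself can serve as the training target.
    The package bundles the network (a temporal U-Net branch plus masked
    dilated-convolution paths over the current frame), a training and
    inference pipeline for multi-page TIFF stacks, a synthetic
    voltage-imaging simulator with known ground truth, baseline and activity
    decomposition and spike detection utilities, and evaluation metrics
    (RMSE, SNR, PSNR, Pearson correlation, spike F1, IoU-thresholded
    extraction F1).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    splines,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
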