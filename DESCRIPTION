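Package: sinoup
Title: Convolutional Angular Upsampling of X-ray CT Sinograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for upsampling undersampled X-ray computed-tomography
    tomograms along the projection (theta) axis. A lightweight three-layer
    convolutional network is trained on one fully sampled tomogram and then
    predicts the projections skipped during rapid time-series acquisition,
    doubling or quadrupling the effective projection count of each sinogram.
    Includes an analytic quadric-primitive phantom simulator with Poisson
    counting noise, NeXus-style HDF5 tomogram input/output, training-patch
    extraction and overlap-average patch merging, a cubic-spline
    interpolation baseline, filtered back projection, and a PSNR/SSIM
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    Rcpp,
    rhdf5,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
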