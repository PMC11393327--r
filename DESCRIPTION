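Package: virtpol
Title: Virtual Birefringence Imaging and Congo Red Staining of Label-Free
    Tissue
Version: 0.1.0
Authors@R:
    person("Virtpol", "Developers", email = "virtpol@example.org",
           role = c("aut", "cre"))
Description: Tools for label-free virtual histological staining of amyloid
    deposits. A single conditional adversarial image-translation network maps
    4-channel autofluorescence images of unstained tissue to brightfield
    Congo-red, cross-polarized birefringence, and angle-shifted birefringence
    renderings, selected at inference time by a constant-valued digital
    staining matrix channel. The package provides a seeded phantom generator
    for paired training data, the two-step (global projective plus pyramid
    elastic) registration pipeline used to build pixel-aligned pairs, the
    generator/discriminator/displacement-field networks with CPU training,
    tile-wise inference with feathered stitching, and a quantitative
    evaluation suite (MAE, MS-SSIM, PSNR, FID, apple-green birefringence
    segmentation with down-sampled IoU, YCbCr color histograms, and nuclei
    statistics via stain deconvolution).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
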