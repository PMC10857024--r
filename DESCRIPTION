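Package: chlorospec
Title: Chlorophyll Estimation from Spectral and Color Vegetation Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for estimating leaf chlorophyll content (SPAD
    units) in greenhouse lettuce from hyperspectral reflectance and RGB
    imagery. Provides a synthetic leaf-spectrum and leaf-image generator for
    benchmarking, spectral preprocessing (standard normal variate and
    Savitzky-Golay smoothing), a registry of 19 spectral and 10 color
    vegetation indices, wet-chemistry chlorophyll calibration against SPAD
    readings, classical leaf segmentation for RGB images, an automated
    model-search regression harness over tree-ensemble families with
    comparison baselines (PLSR, SVM, single-hidden-layer neural network),
    and R-squared/RMSE evaluation reports for single-index, combined, and
    fused spectral-plus-color feature sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    ranger,
    xgboost,
    e1071,
    nnet,
    mixOmics,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
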