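Package: needlespec
Title: RGB-to-Hyperspectral Reconstruction and Needle Nutrient Chemometrics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for in-situ estimation of conifer needle
    nutrients (nitrogen, phosphorus, potassium) from RGB imagery. Renders RGB
    images from 176-band (400-1000 nm) hyperspectral reflectance cubes under
    CIE 1931 / illuminant D65 colorimetry, reconstructs the full cube from RGB
    with a compact multi-scale residual network trained on a mean relative
    absolute error loss (visible and near-infrared halves trained separately
    and merged), extracts foreground mean spectra, and predicts nutrient
    concentrations with multiplicative scatter correction, first-derivative
    preprocessing, competitive adaptive reweighted sampling band selection and
    partial least squares regression. Includes a synthetic pine-canopy scene
    generator so the whole pipeline is testable without the original imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    png,
    yaml,
    signal,
    e1071,
    randomForest,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    mixOmics,
    ggplot2
Config/testthat/edition: 3
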