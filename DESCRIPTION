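Package: fibrilquant
Title: Quantification of Fibrillar Collagen Organization in SHG Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying fibrillar collagen in second-harmonic
    generation (SHG) microscopy of the tumor microenvironment: percent-area
    coverage after global thresholding (per image and by imaging depth),
    gray-level co-occurrence matrix (GLCM) correlation-versus-offset decay
    as a texture-organization readout, and structure-tensor fiber
    orientation analysis with cubic B-spline image gradients, axial
    orientation histograms, peak alignment and alignment frequency.
    Includes a single-hit Poisson limiting-dilution model for estimating
    tumor-initiating cell frequency from transplantation assays, a
    synthetic fiber-phantom generator with exact ground truth for
    validating every statistic, group-comparison statistics, and a batch
    study runner with reproducible CSV/JSON outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    tiff,
    png,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
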