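Package: spermshape
Title: Elliptic Fourier Morphometrics, Fluorescence Metrics and Kinematics
    for Sperm Head Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Outline-based geometric morphometrics of rodent sperm heads:
    elliptic Fourier decomposition of closed head contours with full
    Kuhl-Giardina normalization (translation, scale, rotation and starting
    point), principal component analysis of the coefficient space with
    per-component mean-shape reconstruction, quantification of acrosome
    (PNA-positive) area and nuclear vacuoles from fluorescence channels,
    CASA-style track kinematics (VSL, VCL, VAP) and control-anchored group
    statistics with a/b/c significance letters.  A synthetic-data module
    generates hook-bearing head contours, rendered multi-channel images and
    motility tracks with known ground truth so the whole pipeline is
    testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    multcomp,
    EBImage,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
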