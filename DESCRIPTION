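Package: nvuquant
Title: Neurovascular Histomorphometry from Fluorescence Micrographs
Version: 1.0.0
Authors@R:
    person("NVU", "Quant Developers", email = "nvuquant@example.org",
           role = c("aut", "cre"))
Description: Automated quantification of the neurovascular unit in 2D
    fluorescence micrographs. Re-implements an ImageJ-macro style vessel
    segmentation stack (Gaussian blur, edge detection, local variance,
    median, background subtraction, saturating multiply, invert, particle
    analysis) with faithful 8-bit saturation semantics, plus percent-area
    staining, skeleton-based vessel length and pericyte coverage,
    Laplacian-of-Gaussian cell detection with double-positive
    colocalization, per-animal aggregation with relative-to-control
    normalization, unpaired t / one-way ANOVA with Tukey HSD, linear
    correlation, and a delta-delta-Ct qPCR fold-change pipeline. Includes
    a seeded synthetic micrograph generator that emits exact ground truth
    (masks, centerline lengths, object coordinates) for validation, and a
    batch CLI.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
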