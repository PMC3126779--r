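Package: nucleoquant
Title: Quantification of Nucleolar Fluorescence in Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computer-based quantification of fluorescence signals in
    nucleoli. Implements five alternative strategies to demarcate nucleoli
    in multi-channel fluorescence micrographs (dark/light-hole morphology
    on nuclear-marker, combined-marker or probe images), noise reduction by
    median filtering or binary erode/dilate, statistical background
    correction, size- and intensity-constrained segmentation, per-nucleolus
    and per-nucleus intensity statistics, and a fully automated
    high-throughput-screening scoring mode with Z-factor assay quality.
    Includes a seeded generator of synthetic multi-channel fields and
    plates with ground-truth label masks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
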