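Package: organoidquant
Title: Quantification Pipelines for Cortical Organoid Microscopy and
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the image and expression
    quantification pipelines used to phenotype iPSC-derived cortical
    organoids: 2D fluorescence marker coverage (median filter, background
    removal, H-minima, CLAHE, Otsu), 3D neurite morphometry (Gaussian
    smoothing, local background subtraction, Frangi vesselness,
    skeletonization, fragment statistics), calcium-imaging transient
    detection with exponential kinetics and network synchrony, and
    NanoString-style housekeeping normalization with fold-change
    differential-expression selection, plus qPCR relative expression.
    Synthetic-data generators with ground-truth records emulate every
    input so the pipelines can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
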