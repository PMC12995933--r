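Package: actomorph
Title: Cortical Actin Dynamics, Architecture and Pavement-Cell Shape
    Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of cortical actin in plant epidermal
    cells from fluorescence time series: frame-correlation decay as a
    measure of cytoskeleton dynamics (pairwise Pearson correlation per
    region of interest, Fisher-z normalization at the smallest time lag,
    per-lag group comparison with Benjamini-Hochberg correction), actin
    architecture metrics (occupancy, structure-tensor anisotropy,
    intensity skewness and coefficient of variation) from Hessian-ridge
    enhanced and skeletonized filament masks, and pavement-cell shape
    morphometrics (area, circularity, solidity) from label masks.  A
    synthetic-microscopy generator produces filament movies with known
    turnover, bundling, photobleaching and noise, and lobed-cell label
    mosaics with exact ground-truth polygons, so every stage of the
    pipeline has a recovery test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    tiff,
    jsonlite,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
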