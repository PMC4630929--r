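Package: rootcrown
Title: Root System Architecture Traits from Field Root-Crown Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures root system architecture traits from single 2D
    photographs of excavated, washed root crowns imaged against a dark
    background with a circular scale marker and an identification tag.
    Segments the scene into root, marker and tag, calibrates pixel size
    from the marker, builds the medial-axis skeleton and collar-to-tip
    paths of the root, and computes a registry of 78 traits in four
    categories (common, monocot, dicot, excised), written as
    Excel-compatible CSV and RSML. Includes a threshold calibration
    sweep, a parallel batch runner with per-image fault isolation, and
    a synthetic scene generator with analytically known ground truth.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    parallel,
    optparse,
    png,
    tiff,
    withr,
    matrixStats
Config/testthat/edition: 3
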