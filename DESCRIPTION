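Package: fathom
Title: Persistent Homology of Epicardial Fat Texture in CT Patches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Topological analysis of left-atrium epicardial adipose tissue in
    cardiac CT. Provides Hounsfield-unit window masking and patch handling,
    Vietoris-Rips filtrations of masked pixel clouds, lower-star cubical
    sublevel-set filtrations of grayscale patches, persistent homology by
    boundary-matrix reduction over GF(2), Betti curves, persistence diagrams
    and barcodes, bottleneck distances, and group-level summaries that
    contrast the Betti-number range and diagram-diagonal statistics of fat
    versus non-fat tissue. Includes a seeded synthetic patch generator that
    emulates the two tissue groups, analytic fixtures with known homology,
    brute-force Betti-number oracles for validation, and an end-to-end
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    withr,
    readr,
    utils,
    stats
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
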