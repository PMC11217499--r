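Package: memtopo
Title: Membrane Topography Artefact Correction for Single-Molecule
    Localization Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and corrects apparent molecular clustering in
    single-molecule localization microscopy (SMLM) that is instigated by
    membrane topography rather than by genuine molecular interactions.
    Provides seeded generators for partition-ratio cluster simulations,
    topography-weighted membrane sampling and dimer/detection experiments;
    an image pipeline (histogram rendering, Gaussian smoothing,
    common-mean normalization, membrane-marker subtraction, background
    handling) with an intensity-distribution skewness test; and
    point-pattern statistics including the pair correlation function,
    PC-PALM decomposition into repeat-appearance and protein terms, and
    nearest-neighbour analysis with both continuous and distance-map
    variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    withr,
    EBImage,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    tiff,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
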