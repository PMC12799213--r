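Package: ribbonquant
Title: Quantification of Synthetic Ribbon-Type Active Zones in Cell Culture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image and signal quantification for engineered ribbon-type
    active zones in HEK293 cells. Provides 3D puncta segmentation and
    morphometry (volume, surface area, Wadell sphericity), distance-based
    and pixel-intensity colocalization (Pearson, Manders, Costes
    randomization), membrane-peripherality scoring, stimulus-locked
    delta-F/F calcium imaging analysis, whole-cell IV-curve extraction with
    quality control and Boltzmann activation fits, a statistical decision
    tree for group comparisons, and a seeded synthetic-data generator that
    emulates the imaging and electrophysiology inputs so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
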