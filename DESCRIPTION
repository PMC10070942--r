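Package: morphodyn
Title: Quantitative Cell Morphodynamics in Early Embryogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify single-cell morphodynamics in early embryos
    from 4D labeled segmentations: per-cell volume, surface area, sphericity
    and centroid extraction; cell-cell contact areas and durations;
    spatiotemporal normalization of feature dynamics; detection of mitotic
    rounding and swelling; daughter-volume asymmetry with a
    segmentation-uncertainty band; cross-embryo contact reproducibility and
    neighbor conservation; and pairwise variability metrics with lineage,
    generation, time and contact analyses. Includes lineage annotation of
    nucleus point clouds by PCA alignment and minimum-cost matching, and a
    synthetic-embryo generator (power-diagram geometry inside an ellipsoidal
    eggshell) that provides ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    clue,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
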