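Package: epifold
Title: 3D Vertex Model Simulation and Analysis of Epithelial Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates epithelial folding in columnar tissues with a
    three-dimensional vertex model in which mechanics is governed by apical,
    basal and lateral surface tensions, apical and basal junctional edge
    tensions, elastic attachment of the basal surface to the extracellular
    matrix, and cell volume conservation. Quasistatic tension ramps reproduce
    fold formation by local basal tension decrease or lateral tension
    increase. The package also implements the accompanying quantification
    toolbox: fold cross-section geometry (apical/basal indentation depths and
    cross-sectional lengths normalised by tissue height), in-silico laser
    ablation with first-frame recoil-velocity estimation, per-cell intensity
    ratios, and cross-correlation of relative rates of change between lateral
    F-actin intensity and cell height. Seeded synthetic-data generators
    emulate tracked microscopy tables so every analysis stage is testable
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
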