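Package: meadowsucc
Title: Grazing-Succession Stages, Plant-Soil Coupling and Ecosystem
    Multifunctionality for Alpine Meadow Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quadrat-level surveys of grazed alpine
    meadow. Assigns quadrats to community succession stages by Ward
    clustering on functional-group biomass composition, computes the
    plant-soil coupling coordination degree (min-max standardization,
    PCA-derived indicator weights, subsystem integrals), ecosystem
    multifunctionality and sub-indices by z-score averaging, Camargo
    evenness and gamma diversity, and an inferential layer (one-way ANOVA
    with Tukey HSD letters, simple regressions, Mantel permutation tests,
    correlation matrices, and an averaging-over-orderings R-squared
    decomposition of relative importance). A stage-structured synthetic
    survey generator supports testing and calibration when field data are
    unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    cluster,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
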