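Package: stagecoupling
Title: Stage-Stratified Coexpression Coupling Analysis for Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how transcriptional coupling between a hub
    gene and its targets evolves across ordered disease stages, built around a
    14-gene DDR-collagen-MMP panel in the colorectal adenoma-carcinoma
    sequence. Provides a synthetic expression-data generator with planted
    per-stage coupling (R-squared), fold-changes and batch effects; parametric
    empirical-Bayes location/scale batch correction; stage-stratified Pearson
    correlation tables with Benjamini-Hochberg control, hub coupling
    summaries, trajectory metrics and kinetic classification; one-way ANOVA
    with Tukey HSD post hoc tests and fold-changes; a feed-forward neural
    network stage classifier with batch normalization, dropout and Adam;
    gradient-based Shapley attribution with gene and hub-target interaction
    importance; and STRING-format protein-interaction evidence filtering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    MASS,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
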