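Package: hybridscape
Title: Macroecology of Neophyte and Hybrid Overlap in Vascular Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying the spatial and phylogenetic
    overlap between naturalized alien plants (neophytes) and interspecific
    hybrids. Integrates and filters global checklist tables, builds
    taxonomic-effort covariates (GDP crosswalks and range-weighted
    taxonomist counts), quantifies congener-encounter opportunities for
    hybridization, estimates per-genus net diversification rates with the
    stem-age method-of-moments estimator, computes Blomberg's K
    phylogenetic signal, extracts human-footprint zonal statistics over
    occurrence grids, and fits Bayesian Gaussian and hierarchical
    varying-slope models with posterior contrasts. Ships a synthetic-data
    generator with known ground truth so every stage can be validated
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
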