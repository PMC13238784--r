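Package: strataAGB
Title: Functional and Phylogenetic Diversity Effects on Forest Aboveground
    Biomass Across Tree Strata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links functional identity, functional diversity and phylogenetic
    diversity of overstory and understory tree layers to forest aboveground
    biomass (AGB). Provides allometric AGB estimation from stem inventories
    with a diameter-based stratum split, community-weighted mean traits,
    functional dispersion, convex-hull functional richness and a
    log-trait-variance divergence index, patristic-distance metrics (mean
    pairwise distance, mean nearest taxon distance) and phylogenetic species
    variability/richness, principal component reduction of topographic and
    edaphic covariates, and a partial least squares regression estimator with
    variable importance in projection (VIP) scoring and backward variable
    shaving. A seeded synthetic-community generator with planted
    predictor-AGB effects makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    mixOmics,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
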