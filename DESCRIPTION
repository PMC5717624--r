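Package: phyloniche
Title: Bioclimatic Niche Evolution on Phylogenies with Multi-Regime
    Brownian-Motion and Ornstein-Uhlenbeck Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of bioclimatic-niche evolution for
    island plant radiations and their pollinators. Builds a
    correlation-matrix PCA ordination of a background environmental
    raster, quantifies species niche identity and breadth in the
    ordination space, measures pairwise niche overlap (Schoener's D on
    kernel occupancy grids with availability correction) and explains it
    with linear models compared by AIC, reconstructs discrete regime
    histories (pollination mode, island) with maximum-likelihood Mk
    models and stochastic character mapping, and selects among six
    single- and multi-regime Brownian-motion and Ornstein-Uhlenbeck
    models of niche evolution using small-sample AIC (AICc) weights,
    propagating phylogenetic and occurrence uncertainty by resampling
    trees and jackknifing presence records. Includes a synthetic-data
    generator reproducing the statistical structure of the inputs so
    every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phytools
Config/testthat/edition: 3
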