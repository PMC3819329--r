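Package: corridorgen
Title: Landscape Genetics of Population Connectivity from Microsatellite
    Genotypes and Resistance Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end landscape-genetics toolkit for wildlife
    connectivity studies based on non-invasively collected microsatellite
    genotypes. Covers replicate-based genotyping quality control and
    consensus calling, unique-individual identification with sibling
    probability of identity, genetic diversity and Hardy-Weinberg testing,
    Weir-Cockerham F_ST and allele-sharing (D_SP) differentiation,
    maximum-likelihood pairwise relatedness, Bayesian assignment and
    first-generation migrant detection with a Monte-Carlo resampling null,
    migrant posteriors under a migration prior, construction of raster
    resistance surfaces from habitat, tree cover, night-light and road
    layers, circuit-theory effective resistance between populations, and
    simple and partial Mantel permutation tests linking genetic and
    landscape distance matrices. A synthetic-data module simulates
    genotypes under an F-model, plants known first-generation migrants,
    and generates landscapes with habitat patches, settlements and roads
    so that every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    EBImage
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
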