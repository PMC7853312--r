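Package: pikapop
Title: Genotype-Likelihood Population Genomics for Fragmented Alpine Metapopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A genotype-likelihood-aware population-genomics pipeline for
    reduced-representation (ddRADseq/GBS) data from structured metapopulations,
    motivated by range-wide studies of the American pika (Ochotona princeps).
    Provides SNP panel filtering (completeness, minor allele frequency,
    positional thinning) operating directly on genotype likelihoods, a
    hierarchical Bayesian admixture model fit by Gibbs sampling with DIC-based
    selection of the number of clusters, principal component analysis of
    posterior genotype dosages, Nei's genetic distance, folded
    site-frequency-spectrum estimation with empirical-Bayes nucleotide
    diversity, Watterson's theta and windowed Tajima's D, and landscape
    genetics via multiple regression on distance matrices over geographic,
    elevational and climatic predictors. A synthetic-data module generates
    genotype-likelihood datasets with known truth under a Balding-Nichols
    divergence model, plus co-varying geography and climate tables, so that
    every stage is testable without raw sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    MASS,
    vcfR,
    geosphere
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
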