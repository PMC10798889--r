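Package: csfsubtypes
Title: Molecular Subtyping of Alzheimer's Disease from CSF TMT Proteomics
Version: 0.1.0
Authors@R:
    person("CSF Proteomics", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering molecular patient subtypes from
    tandem-mass-tag (TMT) cerebrospinal fluid proteomics. Implements
    median-adapted internal reference scaling (IRS) normalization across
    16-channel plexes, Kruskal-Wallis screening of disease-related proteins
    (overall and stratified by cognitive state and tau status), consensus
    non-negative matrix factorization subtyping with a three-criterion model
    selection rule (cophenetic coefficient, twofold fit improvement over a
    randomized reference, silhouette), a Louvain coexpression-network
    robustness check, per-subtype differential abundance with estimated
    marginal means and hypergeometric term-set enrichment, and cross-cohort
    subtype prediction with class-balanced (SCUT/SMOTE) random forests.
    Ships a synthetic cohort generator emulating the plex structure, batch
    effects and planted subtypes the analysis assumes, so the whole pipeline
    is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
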