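Package: epinet
Title: Epistatic SNP Interaction Networks for Family-Based Quantitative
    Trait GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A discovery-to-replication pipeline for genome-wide epistatic
    network analysis of quantitative traits in family samples. Provides
    mixed-model (GLMM) score-test association with an empirical genetic
    relationship matrix, pairwise SNP-by-SNP interaction scanning, weighted
    interaction network construction with topological-overlap module
    detection and module-eigengene association, rank-based gene-set
    replication testing, gene-level sum-of-chi-square statistics with
    optional linkage-disequilibrium adjustment, and hypergeometric gene-set
    enrichment. Includes a pedigree-aware simulator of genotypes and
    phenotypes with planted epistatic modules so that every stage can be
    validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
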