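Package: npars
Title: Modular Bayesian Network Construction from eQTL Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Constructs conditional-Gaussian Bayesian networks linking SNP
    genotypes, transcript abundance and a quantitative phenotype by
    network Partition and Reassembly Search (nPARS): every
    (locus, expression, phenotype) triplet is scored exhaustively under a
    closed-form marginal-likelihood network score, triplets are ranked by an
    average network improvement score that balances overall fit against
    phenotype relevance, and high-ranking triplets are reassembled into
    four- and five-node networks by constrained exhaustive search.  Includes
    greedy hill-climbing baselines with random restarts, a node-capped greedy
    variant, a full exhaustive five-node search, simulation generators for
    seven benchmark network scenarios with node/edge sensitivity and false
    discovery rate evaluation, and data-preparation utilities for genotype
    filtering and log-dose cytotoxicity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
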