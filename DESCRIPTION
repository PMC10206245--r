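Package: mirewire
Title: miRNA-mRNA Differential Co-Expression Networks and Rewiring Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative small RNA-seq / RNA-seq analysis pipeline for
    two-condition studies: negative-binomial differential miRNA expression
    with median-of-ratios normalization, canonical seed-site target
    prediction (8mer, 7mer-m8, 7mer-A1, 6mer), per-condition co-expression
    network inference with the PCIT (partial correlation and information
    theory) algorithm, differential connectivity and DyNet-style rewiring
    statistics, intermolecular miRNA:mRNA duplex minimum-free-energy
    scoring with embedded nearest-neighbor parameters, and hypergeometric
    pathway over-representation with Holm correction and kappa-score term
    clustering. Ships a synthetic-data generator with planted ground truth
    (differentially expressed miRNAs, negatively coupled miRNA-target
    pairs with condition-specific rewiring, seed sites, and an enriched
    pathway) so every stage can be validated end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
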