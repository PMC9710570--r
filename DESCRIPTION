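Package: DynAgeNet
Title: Weighted Dynamic Aging-Specific Subnetworks and Supervised
    Prediction of Aging-Related Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@dynagenet.org",
           role = c("aut", "cre"))
Description: Infers weighted dynamic aging-specific subnetworks by
    propagating age-stamped gene expression onto a protein-protein
    interaction network with an expression-biased random walk with
    restart, converts per-age edge fluxes into normalized snapshots and
    differential snapshots, derives per-gene dynamic network features
    (weighted degrees, centralities, graphlet orbit counts, trend
    summaries), predicts aging-related genes with cross-validated
    L2-regularized logistic regression, and analyses prediction overlaps
    and gene-group enrichment in aging-related pathways. Includes a
    synthetic-study generator (scale-free network, planted age-trending
    gene module, microarray-like intensities or RNA-seq-like counts,
    partially hidden positive labels, enriched gene sets) so the whole
    pipeline is testable with a known ground truth, plus TMM count
    normalization and hypergeometric enrichment utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    glmnet,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
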