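Package: lncsom
Title: Single-Cell lncRNA Expression Heterogeneity with Self-Organizing
    Map Portraits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for cell-to-cell heterogeneity of long
    noncoding RNA (lncRNA) expression in single-cell RNA-seq TPM data.
    Implements the log2(TPM+1) transform with two-tier gene filtering and
    cell retention, per-gene z-score normalization, descriptive structure
    analyses (percent-expressed, pairwise correlations, PCA on
    top-variance genes, abundance-union gene panels, hierarchical
    clustering), toroidal hexagonal self-organizing maps with PCA-grid
    initialization, u-matrix cluster seeding, per-cell component
    portraits and hypergeometric gene-set enrichment, splice-variant
    relative-abundance and dominance statistics, a paired-test stemness
    signature with random-set gradient nulls, and molecular-subtype
    scoring with empirical cutoffs and hybrid cell classification. A
    synthetic cohort generator with planted group structure, dropout,
    coexpression modules, a latent stemness gradient, subtype shifts and
    Dirichlet splice-variant proportions makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
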