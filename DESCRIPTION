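Package: celltypewise
Title: Cell-Type-Resolved Comparison of Two Sample Groups from Sparse
    Single-Cell Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares two groups of patients (for example brain versus
    extracranial metastases) at the level of individual cell types using
    sparse single-nucleus or single-cell RNA-seq counts.  Provides an
    imputation-aware masking step that keeps only measured expression
    values, pseudobulk aggregation per patient and cell type with a
    minimum supporting-cell rule, empirical-Bayes moderated t-statistics
    for per-cell-type differential expression, correlation-based
    homogeneity analysis with a random-intercept mixed model,
    signature-gene hierarchical clustering with multiscale bootstrap
    stability, PCA that tolerates missing values (NIPALS), and ranked-list
    gene-set enrichment against a custom background.  A hierarchical
    negative-binomial simulator with planted group effects and
    patient-level random effects makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    yaml,
    mclust,
    ape
Suggests:
    testthat (>= 3.0.0),
    limma,
    lme4,
    knitr,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
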