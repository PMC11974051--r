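Package: deconres
Title: Missing Cell Types in Bulk RNA-Seq Deconvolution and Their
    Recovery from Residuals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how cell types absent from a single-cell reference
    degrade reference-based bulk RNA-seq deconvolution, and recovers the
    missing cell types' proportion signals from the deconvolution residual
    by non-negative matrix factorization. Provides a synthetic-data
    generator with controllable cell-type similarity and depletion,
    pseudobulk construction with known ground-truth proportions,
    signature-matrix building with clip + MinMax scaling, non-negative
    least squares deconvolution, residual computation and factorization
    with NNDSVD-initialised NMF, and cohort-level residual comparisons
    (component t-tests with Bonferroni correction, rank-based distribution
    tests, and PCA with loading-ranked gene lists).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
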