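Package: cscmeta
Title: Meta-Analysis of Cancer Stem Cell Expression Contrasts via
    Molecular Signature Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for meta-analysis of matched test-versus-control gene
    expression contrasts, built around the cancer stem cell (CSC) versus
    non-stem cancer cell setting.  Datasets are quality-screened with a
    principal-component separation score, characterized either by
    differentially expressed genes or by molecular-signature enrichment
    (a running-sum enrichment score with permutation-normalized NES,
    plus parametric PAGE and a pairwise GAGE-style score), clustered
    into genotypes by two-way hierarchical clustering of signature
    profiles with Pearson distance, and summarized by derived gene sets
    (cluster gene sets and up-/down-regulated gene sets selected by
    leading-edge frequency of occurrence) with Fisher exact term
    enrichment.  Includes a synthetic multi-dataset generator with
    planted, directional gene modules so the whole pipeline can be
    exercised and validated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    limma,
    ape
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
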