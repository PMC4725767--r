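Package: proteoSig
Title: Subtype Signatures from Quantitative Tumour Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of super-SILAC quantitative proteomics of
    tumour cohorts: log-ratio expression matrices with explicit missingness,
    valid-value filtering, downshifted-normal imputation of missing-not-at-random
    values, sample correlation structure, rank-based one-dimensional annotation
    enrichment over gene-set hierarchies, one-vs-rest t-tests and one-way ANOVA
    with permutation-based false discovery rate control, and a cross-validated
    support-vector-machine feature-selection framework that extracts minimal
    multi-class protein signatures with ROC/AUC evaluation. Includes a synthetic
    cohort generator with planted markers, enriched categories and
    abundance-dependent missingness for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
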