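Package: relexp
Title: Relative Expression Analysis Classifiers for Two-Class Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rank-based ("relative expression") classification of two-class
    gene-expression data. Implements the Top-Scoring Pair (TSP), k-TSP,
    Top-Scoring Triplet (TST) and Differential Rank Conservation (DIRAC)
    classifiers behind a uniform train/classify/cross-validate contract,
    together with Mann-Whitney gene pre-filtering, Matthews-correlation
    scored repeated stratified k-fold cross-validation, and a cost-aware
    adaptive search over algorithm-parameter configurations. Includes
    readers for CSV expression tables, GEO SOFT (GDS) files with cohort
    subset tags, and GMT gene-set collections, plus a synthetic-data
    generator that plants pair-reversal, triple-ordering and
    network-reranking signals for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
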