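Package: ertargets
Title: Discovery of Persistent Estrogen-Receptor Target Genes and Their
    Survival Association
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing estrogen-receptor (ER) ChIP-seq binding
    between endocrine-responsive and endocrine-resistant breast cancer
    cells and linking persistent binding to patient outcome. Implements
    peak-set filtering and intensity normalization, common/unique overlap
    analysis with a binding-intensity change-ratio filter, gene annotation
    within a TSS window, integration with cell-line differential
    expression, univariate Cox-score gene screening, and Kaplan-Meier /
    log-rank risk stratification with receptor-status subgrouping. A
    synthetic-data generator with planted ground truth exercises every
    stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
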