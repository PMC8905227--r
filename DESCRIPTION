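Package: lincforge
Title: Identification and Functional Analysis of Plant Long Non-Coding RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a genome-wide long non-coding RNA
    (lncRNA) analysis workflow for allotetraploid cotton under sap-sucking
    insect infestation. Provides transcript class-code assignment against a
    reference annotation, the positional/length/expression lncRNA filter
    cascade, open-reading-frame enumeration and a hexamer-based coding
    potential score, negative-binomial differential expression, reciprocal
    best-hit subgenome homolog pairing with a synteny filter, weighted
    co-expression networks with soft-threshold selection and hub detection,
    k-means expression clustering with Fisher-exact term enrichment and
    guilt-by-association function transfer, CRISPR amplicon editing-outcome
    classification, and the small-sample statistics used for phenotype and
    hormone assays. A synthetic two-subgenome data generator with full ground
    truth makes every stage testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
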