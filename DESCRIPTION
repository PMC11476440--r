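Package: triomix
Title: Three-Level Multi-Omics Integration of Transcriptome, miRNA and
    DNA Methylation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates whole-genome bisulfite methylation, mRNA and miRNA
    differential results from two-group designs into a single regulatory
    picture. Provides negative-binomial differential expression calling,
    binomial likelihood-ratio testing of methylated regions, promoter-window
    assignment of regions to genes, miRNA-target anti-correlation filtering,
    a four-way regulatory-category classifier for genes carrying promoter
    methylation together with miRNA targeting, miRNA-centric network and
    co-expression utilities, hypergeometric over-representation analysis,
    and an exact small-sample Mann-Whitney rank test. A synthetic-data
    module generates count, methylation and target-table inputs with
    planted ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    igraph,
    IRanges,
    S4Vectors,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
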