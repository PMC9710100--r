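Package: lncarray
Title: Microarray lncRNA/mRNA Profiling: Normalization, Differential
    Expression, Positional Classification and Cis-Pairing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a two-strain brainstem
    lncRNA/mRNA expression microarray analysis pipeline: quantile
    normalization of probe intensities, two-group differential expression
    with fold-change/P/FDR filters, six-way positional classification of
    lncRNAs relative to coding transcripts, antisense and
    lincRNA-neighbor cis-pairing with direction-concordance statistics,
    hypergeometric over-representation of gene sets, and delta-delta-Ct
    relative quantification of qPCR validation data. Includes a
    synthetic-data generator with planted ground truth (expression
    matrices, toy genome annotations, gene sets, Ct tables) so the whole
    pipeline is testable end-to-end without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite
Config/testthat/edition: 3
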