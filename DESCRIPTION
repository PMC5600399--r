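Package: cageTSS
Title: CAGE Transcription Start Site Peak Calling, Promoter Shape and
    Expression Specificity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for genome-wide analysis of transcription start
    sites (TSSs) profiled by Cap Analysis of Gene Expression (CAGE).
    From per-sample CTSS tag counts it calls TSS peaks with permissive
    and robust support thresholds, normalizes expression (tags per
    million and relative log expression), associates peaks with gene
    models and interval annotations (CpG islands, conserved elements),
    computes promoter shape indices with sharp/broad classification and
    100-bp super clusters, classifies stage-specific and housekeeping
    promoters across an ordered developmental sample series, ordinates
    samples by principal coordinates analysis, and tests promoter
    windows for transcription-factor binding motif enrichment. A
    synthetic 5'-end tag simulator with planted ground truth supports
    end-to-end validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    Rsamtools,
    GenomicAlignments
Config/testthat/edition: 3
RoxygenNote: 7.3.3
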