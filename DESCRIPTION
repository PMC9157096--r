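Package: intronDE
Title: Intron-Signal Classification of Transcriptional and
    Post-Transcriptional Differential Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Uses intron-mapping reads in total-RNA rRNA-depleted RNA-seq
    libraries as a readout of nascent transcription to partition
    differentially expressed genes into transcriptionally and
    post-transcriptionally regulated classes between two conditions.
    Builds genome-wide non-overlapping exon and intron segment catalogs
    from GFF3 gene models, assigns aligned reads to per-gene exon or
    intron features, runs a self-contained negative-binomial Wald test
    per feature class, applies intron/exon-evidence classification
    rules, and joins the calls against auxiliary gene annotations
    (enhancer-linked genes, transcription-factor target networks,
    subgenome assignments, gene ontology maps) with hypergeometric
    enrichment. Ships a synthetic-data generator with known ground
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
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
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
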