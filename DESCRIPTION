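Package: nascentcycle
Title: Cell-Cycle-Resolved Nascent Transcription and Nucleosome Maturation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for spike-in normalized NET-seq nascent
    transcription across the budding-yeast cell cycle and for nucleosome
    maturation on newly replicated chromatin. Implements the two-stage
    spike-in/depth normalization chain, region quantification with
    fold-change flagging at fixed FC/FDR thresholds, RNA polymerase II
    distribution statistics (5'/3' ratio with exact Mann-Whitney
    comparison, expression-normalized metagene profiles, length-ordered
    log2 fold-change heatmaps), replication-timing gene classification
    with time-course summaries of gene-dosage buffering, and TSS-aligned
    nucleosome dyad profiling with peak/trough and linker-length metrics.
    A seeded synthetic-data generator emulates the study designs at desk
    scale with recorded ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
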