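Package: mirmotifs
Title: Structural and Motif Analysis of Mature microRNA Sequence Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural analysis of mature microRNA (miRNA) sequence sets:
    length-distribution statistics, per-position nucleotide composition,
    purine/pyrimidine content profiling, exhaustive presence-based k-mer
    motif discovery (including maximal long shared motifs), consensus-motif
    grouping of miRNAs sharing long anchors, motif-to-target-gene overlap
    summaries against validated interaction maps, and cross-species motif
    conservation tables. Includes a seeded synthetic-data generator that
    emulates the empirical length distribution and positional nucleotide
    biases of myeloid-cancer miRNA sets, with planted motifs and coupled
    target maps, so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
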