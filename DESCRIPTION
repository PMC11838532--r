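Package: cifi
Title: Multi-Way Chromatin Contact Analysis for Long-Read 3C Concatemers
Version: 0.1.0
Authors@R:
    person("CiFi", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for concatemer-based chromosome conformation capture (3C)
    with long HiFi reads: in-silico restriction digestion of reads and
    reference genomes, per-segment alignment ingestion, expansion of each
    read's monomers into all pairwise chromatin contacts, 4DN pairs output,
    binned sparse contact matrices with Knight-Ruiz balancing, distance-decay
    and MAPQ-by-annotation QC, window-signal TAD calling with partition
    concordance (MoC), and a concatemer-read simulator with truth tables so
    the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
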