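Package: chimeradetect
Title: Detection, Simulation and Benchmarking of Chimeric RNA Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects chimeric transcripts (fusion genes, read-throughs,
    trans-splicing candidates) from aligned paired-end RNA-seq data by
    clustering split reads into oriented splice-junction candidates,
    attaching discordant mate-pair evidence split into consistent and
    inconsistent support, filtering on two-tier read support, parent-gene
    identity and exonic sequence homology, and classifying each junction
    as read-through, intrachromosomal, inverted, interstrand or
    interchromosomal. Ships a chimera simulator that emits chimeric and
    background transcripts with truth junctions, paired reads and truth
    alignments, and a two-level (gene-pair and junction) benchmark with
    sensitivity, precision, F1 and junction-distance metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
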