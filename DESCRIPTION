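Package: ribocall
Title: Translation Calling from Ribosome Profiling with Binomial Framing Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls productive translation of canonical open reading frames
    (ORFs), short coding sequences and upstream ORFs (uORFs) from aligned
    ribosome footprints and matched RNA-Seq across developmental stages.
    Builds an ORF catalog from GFF3 annotation and genome sequence, computes
    per-ORF RPKM and translational efficiency, detects triplet periodicity
    of footprint 5' ends and scores per-ORF framing with an exact binomial
    test, applies a transcription / ribosome-binding / framing decision
    ladder per stage, flags translational regulation between contiguous
    stages with TE Z-ratios, and scores start-codon (Kozak) context,
    amino-acid composition and in-silico tryptic detectability of ORF
    peptides. Includes a seeded synthetic-data generator that emulates the
    statistical structure of staged Poly-Ribo-Seq libraries so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    graphics,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
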