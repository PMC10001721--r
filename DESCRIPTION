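Package: mitosrna
Title: Identification, Quantification and Annotation of Mitochondria-Derived
    Small and Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and annotates RNAs transcribed from the mitochondrial
    genome in adapter-trimmed short-read sequencing libraries. Reads from many
    FASTQ files are collapsed into a unique-sequence count matrix, placed on
    the mitochondrial genome with best-hit, at-most-one-mismatch semantics,
    rescued when they carry a non-templated 3' CCA addition, and annotated
    against the mitochondrial gene set: gene assignment, location class,
    tRNA-derived fragment subtype (tRF-5/tRF-3/tRF-1/i-tRF/tRH), strand,
    orientation, substitutions, and a two-level nomenclature identifier.
    Long non-coding transcripts (>= 50 nt) are additionally grouped by shared
    5' end so that 3' length variants are summed. A ground-truth read
    simulator and an element-wise concordance checker allow the whole
    pipeline to be validated round-trip.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
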