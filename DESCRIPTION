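Package: crisprascan
Title: CRISPRa sgRNA Design from Promoter Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates, classifies, scores and ranks candidate single-guide
    RNAs (sgRNAs) for CRISPR activation (CRISPRa). Given genome sequences
    (FASTA) and transcription start sites (GFF3 or BED), the package scans
    promoter windows for protospacers with a configurable PAM on both
    strands, annotates each candidate with its distance to the TSS, spacer
    GC fraction and targeted DNA strand (template versus non-template), and
    ranks candidates with a rule-based composite score in which placement
    relative to the TSS dominates GC content and strand preference. Includes
    a GC-to-fold-activation calibration, a poly-T (pol III terminator)
    filter, TSV/BED reporting, a seeded synthetic-genome fixture generator
    with planted guides and ground truth, and a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
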