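Package: ribotype
Title: Cell-Type-Resolved Ribosome Profiling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for comparative Ribo-seq/RNA-seq
    studies of translational regulation between cell types (e.g. neurons
    versus glia). Builds transcript region models (5' leader, CDS, 3' UTR)
    from GTF/GFF and FASTA, assigns ribosome P-sites from footprint 5' ends
    with length-dependent offsets, quantifies region-resolved footprint
    densities (raw counts, RPM, TPM), computes translational efficiency (TE)
    and 5' leader/CDS density ratios, calls differentially translated
    transcripts between two cell types, aggregates metagene profiles around
    start codons and upstream AUGs, annotates upstream start codons and
    minimal six-base uORFs, and scores per-codon footprint accumulation
    (ribosome stalling). A seeded synthetic-data generator emits paired
    transcriptome annotation, footprints and RNA counts with known ground
    truth so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    Rsamtools,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
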