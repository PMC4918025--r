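Package: ribopipe
Title: Ribosome Profiling Pipeline: P-Site Calibration, Footprint
    Counting and Pause-Score Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for ribosome profiling (Ribo-seq) data that goes
    from aligned footprints (BAM) to quantification. It builds transcript
    models with 5'UTR/CDS/3'UTR boundaries from a GTF annotation, inspects
    the footprint length distribution, calibrates the per-read-length
    offset between a read end (5' or 3') and the ribosomal P-site using
    metagene profiles anchored at the translation start site of highly
    expressed transcripts, shifts reads to P-sites, counts footprints per
    transcript region and per codon, quantifies one- to three-codon
    motifs, performs PCA of codon occupancy, and computes per-ORF pause
    scores for stalling motifs such as Pro-Pro-X. A synthetic-data
    generator with planted offsets, expression heterogeneity and stall
    sites makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    parallel,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
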