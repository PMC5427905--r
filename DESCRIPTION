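Package: vegfsplice
Title: Junction-Probe Scanning and Splice-Junction Quantification for
    VEGFA Isoforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify evidence for alternative splice junctions of
    the VEGFA gene in RNA sequencing data, centred on the question of whether
    transcripts using the distal exon-8b acceptor (the VEGFA_xxx_b isoform
    family) are present. Builds exon-junction probe sequences from a locus
    model and scans raw reads for exact probe matches; extracts, annotates
    and filters splice-junction records in the 9-column STAR SJ.out.tab
    dialect; performs anchor-based spliced read assignment that reproduces
    and then eliminates the short-overhang misalignment artifact caused by
    shared terminal sequence between exon 7 and exon 8a; predicts and
    classifies RT-PCR amplicons in silico; and computes detection-limit and
    isoform-ratio statistics. A seeded synthetic-locus and read simulator
    makes the full pipeline testable without external genome or read data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
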