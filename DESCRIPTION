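Package: rhoscreen
Title: Design, Simulation and Analysis of In Utero Pooled shRNA
    Morphogenesis Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled short-hairpin RNA (shRNA) screens of
    embryonic skin morphogenesis, in which lentivirally transduced
    epidermal progenitors are followed into the epidermal and
    hair-follicle fractions.  Provides a clonal founder-expansion
    simulator with known ground truth, hairpin quantification from
    amplicon FASTQ (barcode demultiplexing, 21-nt trimming, exact or
    one-mismatch matching, zero-read filtering), scrambled-control
    normalized log2 fold changes, replicate statistics with
    Benjamini-Hochberg false discovery rate control, gene-level hit
    calling and fraction classification, a screen coverage/power
    calculator, two-color competition-assay analysis, a BioID
    replicate-presence interactome filter, and planar-cell-polarity and
    morphometric quantification utilities.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
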