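Package: fragrec
Title: Competitive Fragment Recruitment Analysis of Metagenomic Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for competitive fragment recruitment analysis (FRA) of
    metagenomic reads against a multi-genome reference database, including
    a BLAST-tabular importer, a built-in seed-and-extend local aligner,
    the full hit-filter cascade (e-value, identity and coverage thresholds,
    within-genome deduplication, ribosomal-operon masking, best-genome
    assignment), identity binning, recruitment-rate normalization per
    genomic megabase and sequencing depth, recruitment plots and heatmaps.
    Also provides marker-gene microdiversity utilities (amplicon merging,
    end-gap-free pairwise identity, haplotype census, reference screening)
    and proteorhodopsin annotation (key functional residues, spectral
    tuning classification, transmembrane helix prediction), together with
    a synthetic-data generator that emulates multi-genome communities of
    known average nucleotide identity, read sets of controlled identity,
    marker families and rhodopsin-like proteins with ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
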