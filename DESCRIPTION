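Package: rafamp
Title: Barcoded Amplicon Deep-Sequencing Analysis of B-RAF Hotspot Mutations
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection and quantification of B-RAF hotspot mutations in mixed
    cell populations from barcoded, pyrosequencing-style amplicon deep
    sequencing. Provides a seeded read simulator with per-base substitution
    and homopolymer indel errors, barcode demultiplexing, an indel-tolerant
    semi-global aligner, count-based variant calling with relative mutation
    abundance (RMA), Wilson confidence intervals, exact-binomial detection
    thresholds and limits of detection, codon-level protein-consequence
    annotation (including in-frame insertions), somatic-versus-germline
    compartment classification with cohort statistics, and a residue-contact
    analysis of kinase activation-segment mutants at a 6 Angstrom cutoff.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    Rcpp,
    bio3d,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
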