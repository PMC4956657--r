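Package: mircms
Title: Small RNA-Seq miRNA Discovery and Two-Library Differential
    Expression for Cytoplasmic Male Sterility Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for comparative small-RNA sequencing of a
    cytoplasmic male sterile (CMS) line and its fertile maintainer:
    read cleaning and tag collapsing, classification of tags against
    structural non-coding RNA and known mature miRNA references,
    prediction of novel miRNA hairpins from unannotated tags with
    duplex/star criteria, exact two-library (Audic-Claverie) tests of
    differential expression on per-million normalized counts, plant
    miRNA target prediction by complementarity scoring, and export of
    the miRNA-target regulatory network. A fully-specified synthetic
    data generator plants known miRNAs, hairpin loci and per-miRNA
    fold changes so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
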