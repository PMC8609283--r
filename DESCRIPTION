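Package: isoscope
Title: Structural Classification and Splicing Analysis of Long-Read Transcript Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis toolkit for long-read (Iso-Seq style)
    transcript models. Classifies query transcripts against a reference
    annotation into the standard structural categories (FSM, ISM, NIC, NNC,
    fusion, antisense, intergenic, genic genomic, genic intron), applies
    artifact filters (5' degradation fragments, intrapriming), annotates
    CAGE-peak proximity, polyA motifs and intron retention, enumerates local
    alternative-splicing events (SE, MX, A5, A3, AF, AL) from splice-junction
    coordinates, predicts ORFs, coding potential (Fickett TESTCODE) and
    nonsense-mediated-decay candidacy, normalizes full-length read counts to
    TPM, computes transcript-diversity and rarefaction statistics, and calls
    threshold-based differential transcript expression and usage. A seeded
    synthetic-data generator plants ground-truth categories, splice events,
    ORF/NMD structure, artifacts and isoform switches so that every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    BiocGenerics,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
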