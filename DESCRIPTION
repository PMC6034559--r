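Package: raretaxa
Title: Marker-Based Detection and Quantification of Rare Gut Commensals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for detecting and quantifying a rare gut
    commensal (segmented filamentous bacteria, SFB) from heterogeneous
    evidence: subtractive pan-genome discovery of clade-specific marker
    genes, primer design with in-silico PCR specificity screening, absolute
    qPCR quantification with a positivity threshold and a metagenomic
    detectability calculator, clade-unique tryptic peptide identification,
    and cohort-level statistics linking colonization to mucosal immune
    readouts. A synthetic-data module generates every input with planted
    ground truth so the full workflow is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    tools,
    utils,
    vegan
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
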