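Package: regmotif
Title: Feedback Motifs in Transcription Factor and microRNA Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted gene regulatory networks from transcription factor
    ChIP-seq binding peaks and curated microRNA target tables, enumerates
    autoregulation and microRNA/TF feedback motifs (M1-M4), tests their
    enrichment against degree-preserving edge-rewiring null models with
    empirical p-values, and scores motif conservation across tissue-specific
    sub-networks. Includes a synthetic-data generator that emulates the
    structure of ReMap-style peak collections, cis-regulatory modules,
    gene annotation and miRNA target tables with planted ground-truth
    network structure, so every pipeline stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    IRanges,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
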