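Package: trfnet
Title: tRNA-Derived Fragment Classification and Small RNA Regulatory
    Network Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for tRNA-derived small RNAs (tRFs and
    tiRNA halves) in two-group small-RNA sequencing designs. Classifies
    reads aligned to mature and precursor tRNA references into the six
    positional fragment classes (tRF-5, tRF-3, tRF-1, i-tRF, tiRNA-5,
    tiRNA-3), computes counts-per-million normalized differential
    expression with class-specific fold-change thresholds, predicts
    sncRNA target sites on 3'UTRs with a seed-weighted local-duplex
    score, builds anti-correlated sncRNA-mRNA bipartite regulatory
    networks with hub ranking and transcription-factor annotation,
    performs hypergeometric (EASE-style) gene-set enrichment, and
    quantifies qPCR validation data by the 2^-ddCt method. A synthetic
    data generator with planted ground truth supports end-to-end testing
    of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
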