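Package: vagitax
Title: Full-Length 16S rRNA Nanopore Profiling of Low-Diversity Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tested, self-contained implementation of a rapid full-length
    16S rRNA nanopore amplicon profiling workflow: quality and length
    filtering with low-complexity masking, host-read screening, per-read
    best-hit taxonomic classification with even allocation of score ties,
    composition tables with an "Others" rule, Shannon diversity, Nugent-score
    categorization, weighted UniFrac distances with principal coordinate
    analysis, in-silico PCR with degenerate primers, and a deterministic
    mock-community read simulator that makes every stage verifiable at desk
    scale. All user-facing functions take and return tibbles.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    phyloseq,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
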