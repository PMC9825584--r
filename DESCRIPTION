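Package: orthogs
Title: Delineation, Mapping and Benchmarking of Hierarchical Orthologous Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for desk-scale delineation of orthologous groups (OGs)
    from per-species proteomes: all-vs-all local alignment homology search
    with a k-mer prefilter, best-reciprocal-hit (BRH) candidate detection
    with optional in-paralog attachment, clustering of candidates into OGs
    at named levels of a species tree (flat per-level mode or hierarchical
    tree mode), mapping of novel gene sets onto precomputed OGs,
    phylogenetic-profile annotations (universality, duplicability,
    single-copy fractions) with web-style filters, MinHash genome sketching
    with Mash-style identity clustering for genome sampling, and a
    benchmarking module computing best-combination precision/recall/F1,
    exact/akin/split categories and the Variation of Information against
    reference OG sets. Includes a gene duplication-loss-divergence
    simulator along a species tree that provides ground-truth OGs for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
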