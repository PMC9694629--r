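Package: mitorecomb
Title: Repeat-Mediated Recombination Analysis for Multipartite Plant
    Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects repeat pairs in circular multi-chromosomal
    mitochondrial genomes, builds the four junction conformations (two
    major, two minor) around each repeat by flank switching, classifies
    spanning long reads to estimate per-repeat recombination frequencies,
    predicts the circular rearrangement products (splits, inversions,
    fusions) of recombination, scans microsatellites with MISA-style
    thresholds, and identifies plastid-derived insertions (MTPTs).
    Includes a deterministic synthetic-data generator (genomes,
    conformation mixtures, noisy long reads) so every stage can be tested
    against planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    methods,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
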