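Package: censcape
Title: Centromere Sequence Landscapes in Fission Yeast Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative analysis of centromeric sequence features in
    fission yeast genomes. Computes GC-composition-normalized 5-mer
    enrichment z-scores for sliding genome windows against a
    base-shuffle permutation null, classifies windows into chromatin
    groups (CENP-A core, centromeric heterochromatin, subtelomere,
    mating-type locus, neocentromere, other) from peak intervals,
    performs principal component analysis of enrichment profiles with
    95% group ellipses and between-group rank tests, detects tRNA gene
    clusters by greedy chaining with a genome-shuffle permutation
    significance test and false-discovery-rate control, computes
    minichromosome establishment and per-division loss-rate statistics
    from colony counts, and generates synthetic genomes with planted,
    GC-matched compositionally biased domains for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
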