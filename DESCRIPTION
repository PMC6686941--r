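Package: bitqg
Title: Bit-Packed Forward-in-Time Simulation of Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Forward-in-time quantitative-genetics simulator built on a
    binary encoding of diploid genomes. Each chromosome is stored as a pair
    of bit-packed strands over the loci of a genetic map; meiosis is
    simulated by constructing crossover bit masks from sampled chiasma
    positions and recombining the strands with a single bitwise statement.
    Provides founder construction, crossing, self-crossing and doubled
    haploids, pluggable recombination models (count-location, independent
    segregation, hotspots), infinitesimal traits and phenotype simulation at
    a target heritability, VanRaden realized genomic relationships, pedigree
    additive relationships by the tabular method, a single-kernel REML
    variance-component solver, and an end-to-end F2:3 variance-partitioning
    study, plus delimited/VCF export and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
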