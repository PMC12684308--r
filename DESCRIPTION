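Package: rescuelab
Title: Forward Simulation and Genomic Analysis of Long-Term Genetic Rescue Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-based forward-time simulator of a three-tier
    Drosophila genetic-rescue design (large base population, moderate-size
    derived populations, small rescued and non-rescued lines) together with
    the estimators used to analyse such experiments: the inbreeding
    depression rate with bootstrap errors, nucleotide diversity and
    Watterson's theta, Tajima's D, runs-of-homozygosity calling with a
    false-positive-controlled minimum-SNP rule, derived-allele load
    profiles normalised by fourfold-synonymous counts, recombination-rate
    stratification, and line survival curves with interval extinction
    rates. All user-facing functions take and return data frames so
    analyses compose with the pipe.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
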