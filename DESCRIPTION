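Package: haplosweep
Title: Selective-Sweep Inference for Deletion-Tagging Haplogroups from
    Phased Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether a high-frequency haplogroup that tags
    a structural variant bears the signature of an incomplete selective
    sweep. Provides an ms-compatible coalescent simulator with
    recombination, migration and demographic events; nucleotide diversity,
    Watterson's theta, Tajima's D, Weir-Cockerham FST, haplotype r-squared
    and run-of-homozygosity statistics; frequency-matched simulated null
    distributions for FST, carrier diversity and ROH; empirical
    random-region nulls with rank-sum tests; haplogroup identification and
    deletion imputation; three non-selective age estimators; and a
    synthetic phased-panel generator with ground-truth labels so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
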