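Package: mtabc
Title: Ancient mtDNA HVR-I Population Genetics and Serial-Coalescent ABC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of ancient mitochondrial
    HVR-I haplotypes: motif parsing and haplogroup assignment, haplogroup
    frequency spectra and their principal component analysis, haplotype
    diversity and AMOVA-based fixation indices, exact haplotype sharing
    between ancient and modern population pools, and a serial (heterochronous)
    coalescent simulator with a finite-sites HVR-I mutation model.
    Demographic hypotheses of genetic continuity versus migration are compared
    by rejection-based approximate Bayesian computation with AIC and Akaike
    weights. Synthetic-data generators emulate modern comparative pools so the
    whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
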