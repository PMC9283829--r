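Package: fetoscope
Title: Non-Invasive Fetal Genotype Reconstruction from Maternal Plasma cfDNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs a fetal genome non-invasively from maternal-plasma
    cell-free DNA allele counts together with phased parental genotypes. A
    per-locus Bayesian posterior over maternal-fetal genotype combinations is
    combined with relative-haplotype-dosage classification (a sequential
    probability ratio test accumulated along parental haplotype blocks) and
    closest-variant imputation, with per-category dispatch of the two engines
    and Bayesian gap-filling. Includes a fetal-fraction estimator, a trio and
    plasma-count simulator with recombination and configurable haplotype-block
    N50 for end-to-end validation, and accuracy accounting in the standard
    per-category report format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
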