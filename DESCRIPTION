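Package: apaflow
Title: Alternative Polyadenylation Isoform Usage, Enhancer Enrichment and
    Reporter Calculus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for short versus long 3'UTR isoform usage in
    two-condition RNA-seq designs. Computes poly(A) site usage (PAU) and its
    between-condition difference (dPAU) from isoform-level counts and TPM,
    runs negative-binomial gene-level and beta-binomial isoform-usage
    differential tests with Benjamini-Hochberg FDR control, classifies
    multi-UTR genes into gene-up / SU-up categories, tests enrichment of
    enhancer-associated genes per category by Pearson chi-square, and
    controls for expression differences with stratified expression-matched
    resampling. Includes a negative-binomial / beta-binomial synthetic-data
    generator with planted ground truth, and the luciferase reporter
    calculus (transcriptional activity, CPA activity, read-through,
    exponential mRNA decay fitting, nascent fraction, screen-hit banding).
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
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
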