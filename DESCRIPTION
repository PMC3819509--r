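Package: fagwas
Title: Bayesian Whole-Genome Regression, 1-Mb Window GWAS and Genomic
    Prediction for Fatty-Acid Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Spike-and-slab Bayesian whole-genome regression (BayesB and
    BayesC variants) for fatty-acid composition traits, with 1-Mb window
    genome-wide association (window genetic variance and posterior
    probability of inclusion), direct genomic breeding values, VanRaden
    genomic relationships with K-means cross-validation and realized
    accuracy, within-window trait-pair correlations to probe pleiotropy,
    and derivation of composite fatty-acid traits and indices on beef and
    fat-percent bases. Includes a synthetic-data generator emulating a
    50K-chip beef-cattle study design so the whole pipeline is testable
    without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
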