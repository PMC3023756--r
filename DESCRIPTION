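Package: cnvmix
Title: Bayesian Spatial Mixture Calling of Integer Copy Number from
    SNP-Array Log2-Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers integer genomic copy number from ordered SNP-array
    log2-ratios with a Bayesian spatial normal mixture model. The number
    of mixture components is unknown and is sampled by reversible-jump
    MCMC; spatial smoothness of the mixture weights is induced by
    Gaussian Markov random fields over SNP positions; component means
    follow a contamination-aware signal model in which normal-cell
    admixture shrinks aberrant log2-ratios toward zero. Ships a scenario
    simulator and misclassification, false-negative and false-positive
    rate evaluation, per-SNP posterior class probabilities, segment
    output in BED-like form, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
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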