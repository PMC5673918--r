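Package: ulpcna
Title: Tumor Fraction and Copy Number from Ultra-Low-Pass Whole-Genome
    Sequencing of Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimates circulating tumor DNA fraction, tumor ploidy, and
    large-scale somatic copy-number alterations from ultra-low-pass (~0.1x)
    whole-genome sequencing of cell-free DNA, without a matched normal sample.
    Read counts in 1 Mb bins are corrected for GC-content and mappability bias,
    normalized against a healthy-donor reference panel, and modeled with a
    Bayesian hidden Markov model with Student's-t emissions whose state means
    couple integer copy number to global tumor fraction and ploidy; parameters
    are estimated by MAP expectation-maximization over multiple restarts.
    Includes a synthetic ULP-WGS generator, in-silico tumor/normal mixture
    constructions, benchmark metrics with exact binomial confidence intervals,
    and a theoretical power calculation for calibrating exome sequencing depth
    of cell-free DNA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
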