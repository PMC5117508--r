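Package: transcriptogram
Title: Transcriptogram Analysis of Expression Data on Functionally Ordered Gene Lists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders genes along a one-dimensional list by simulated annealing
    over a protein-association network, projects expression data onto the
    ordered list with a sliding-window average (the transcriptogram), and
    compares sample classes with relative transcriptograms, position-wise
    Welch tests and permutation-based false discovery rates. Companion stages
    provide single-gene volcano analysis, gene-set mean-expression
    comparisons, and a microarray preprocessing chain (min-shift, log2,
    quantile normalization, limit-of-detection and low-range filtering,
    replicate-probe averaging). A synthetic-data module generates modular
    interaction networks, pathway annotations and replicate expression with
    planted perturbations so the whole pipeline can be exercised offline with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    fgsea,
    generics,
    ggplot2,
    limma,
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
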