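Package: abcbench
Title: Approximate Bayesian Computation with Conjugate and Coalescent Benchmarks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rejection, k-nearest-neighbour and pseudo-marginal MCMC samplers
    for approximate Bayesian computation (ABC), together with the summary
    statistics and discrepancy measures (Euclidean, Wasserstein-1, kNN
    Kullback-Leibler) needed to drive them. Includes a conjugate
    Normal-Inverse-Gamma benchmark with a closed-form posterior oracle for
    studying ABC's approximation, information-loss and Monte-Carlo errors; a
    Kingman coalescent simulator with exponential growth and infinite-sites
    mutation; the classical population-genetics summaries (pairwise diversity,
    segregating sites, Tajima's D, Fay-Wu's H); and seeded experiment drivers
    that emit tidy result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    parallel,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
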