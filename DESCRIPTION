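Package: opirt
Title: Explanatory Item Response Models with Operation-Specific Learning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Bayesian estimation and evaluation of a family of explanatory
    item response models in which the difficulty of the cognitive operations
    required by test items changes with accumulated practice during the test:
    the Rasch model, the linear logistic test model (LLTM), and
    operation-specific learning models with non-contingent (OSLM),
    contingent (OSCLM) and differential contingent (OSDCLM) practice effects.
    Includes Hamiltonian Monte Carlo estimation with convergence diagnostics,
    empirical identifiability checks based on response-pattern coefficient
    matrices, posterior predictive model checking with odds-ratio and
    Bayesian latent residual discrepancies, WAIC and PSIS-LOO model
    comparison, and a factorial simulation-study harness for parameter
    recovery and model-selection performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    ggplot2,
    rlang,
    statmod
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    coda,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
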