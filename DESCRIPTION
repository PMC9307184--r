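Package: bracod
Title: Bayesian Regression Analysis of Compositional Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies bacterial taxa associated with a continuous
    physiological outcome (for example faecal butyrate concentration) from
    compositional relative-abundance data. Fits a fully Bayesian linear
    regression with stochastic search variable selection (spike-and-slab
    priors) in which the unobserved per-sample total abundance is
    marginalized out of the likelihood, so that inference is performed
    directly on relative abundances without a pre-transformation. Includes
    a lognormal-multinomial community simulator with known contributor
    coefficients, benchmarking utilities (confusion metrics, ROC curves,
    centred-log-ratio LASSO and spike-and-slab comparators) and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
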