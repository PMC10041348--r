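Package: bbmiss
Title: Hierarchical Bayesian Non-Response Models for Forensic Black-Box Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Error-rate estimation for forensic black-box studies with high
    unit and item non-response. Provides beta-binomial hierarchical models for
    examiner-by-item binary decision panels: a naive complete-data model, an
    ignorable-missingness model, and a non-ignorable selection model in which
    the probability of responding to an item depends on whether the (possibly
    unobserved) decision would have been an error. Includes empirical-Bayes
    hyperparameter estimation by marginal maximum likelihood, bespoke
    conjugate data-augmentation Gibbs samplers, batch-means Monte Carlo
    standard errors and the multivariate Gelman-Rubin diagnostic,
    posterior-predictive study error proportions, exact Clopper-Pearson
    baselines, and a synthetic black-box-study generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
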