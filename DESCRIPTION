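Package: olfthresh
Title: Design and Reliability Analysis of Short Olfactory Threshold Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating short psychophysical
    olfactory threshold tests based on three-alternative forced-choice
    (3AFC) dilution series such as the Sniffin' Sticks n-butanol test.
    Implements the 3AFC logistic item response model with a 1/3 guessing
    floor, simulators for adaptive staircase and constant-stimuli
    protocols, marginal maximum-likelihood fitting of the random-effects
    model with Gauss-Hermite quadrature, empirical-Bayes threshold
    estimation with multiple imputation for non-response, and a
    Monte-Carlo replication engine that estimates the reliability of a
    candidate protocol for a specified population threshold distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
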