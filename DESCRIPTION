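Package: seqbf
Title: Sequential Bayes Factors and Posterior-Odds Calibration Under
    Optional Stopping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Posterior-odds (Bayes factor) engines for five standard
    hypothesis pairs (normal mean with known variance, normal mean with
    Jeffreys variance prior, the JZS one-sample t test with a Cauchy
    effect-size prior, Zellner-Siow g-prior linear regression, and the
    Bernoulli model with Jeffreys' Beta(1/2,1/2) prior), together with
    seeded replicate-stream generators, an optional-stopping engine with
    threshold rules, calibration diagnostics comparing nominal against
    observed posterior odds, and frequentist operating characteristics
    (universal-bound type-I error control and sequential-design type-II
    error) of Bayes-factor stopping rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
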