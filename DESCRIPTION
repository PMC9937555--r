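Package: structest
Title: Tests for Rejecting the Structural Interpretation of a Latent
    Factor Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generalized-method-of-moments tests of whether a univariate
    latent factor model admits a structural (causal) interpretation, i.e.
    whether an external discrete variable Z is independent of a set of
    indicators given the latent. Provides a reliability-dependent
    distance-metric test with a plug-in variance correction for estimated
    reliabilities, a reliability-free rank-1 test on group-mean contrasts,
    estimation of indicator reliabilities from pairwise covariances
    (including a quasi-Poisson log-link formulation), a synthetic-data
    generator for the basic factor model under null and alternative
    mechanisms, and a Monte-Carlo harness for type-I error, power and
    chi-square calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
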