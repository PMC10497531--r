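Package: darkcore
Title: Approximating the Common Core of Aversive Personality from Trait Subsets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how well subsets of aversive personality
    traits approximate the common core (the general factor D) of all
    aversive traits. Implements maximum-likelihood estimation of
    orthogonal bifactor models from covariance matrices with standard fit
    indices (chi-square, RMSEA with 90% CI, SRMR), regression-method
    general-factor scores, explained common variance (ECV) per trait
    scale, exhaustive enumeration of trait subsets with reduced-model
    refits, and correlation-based summaries of approximation quality.
    Includes a synthetic Likert-data generator with a known bifactor
    population structure so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
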