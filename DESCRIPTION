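Package: emergentdrf
Title: Emergent First-Order Dose-Response Models for Chronic Stressors and
    Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantal dose-response modelling for chronic chemical and other
    health stressors based on an emergent first-order (multiplicative) model of
    illness progression. Provides the shifted Frechet dose-response function
    and its dissimilar-mode (response-mixing) and common-mode (background
    "dose") background-risk variants, common-mode mixture models with pairwise
    interaction terms and a shared threshold, dissimilar-mode mixture models
    combining interaction-adjusted effective doses by inclusion-exclusion
    under independence, and the classical multistage and lognormal models for
    comparison. Models are fitted to quantal dose-group data by minimising the
    binomial deviance with multi-start bounded optimisation, and goodness of
    fit is assessed by a chi-square test on the deviance. A simulator
    reproduces the autocorrelated multiplicative cause chain that generates
    Weibull-distributed illness severities and Frechet-distributed critical
    doses, and draws binomial quantal datasets from any model in the family
    for parameter-recovery and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
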