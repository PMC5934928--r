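Package: svensson36
Title: Svensson's Method for Paired Ordinal Data with RAND-36 Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rank-invariant analysis of paired ordered categorical data by
    Svensson's method (percentage agreement, relative position, relative
    concentration, relative rank variance, with jackknife standard errors,
    normal-approximation confidence intervals and ROC points of the cumulative
    marginal distributions), RAND-36 Health Survey scoring with a strict
    complete-case rule, internal consistency via ordinal (polychoric) alpha,
    and a latent-trait generator of synthetic two-occasion cohorts for
    test-retest reliability and responsiveness designs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
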