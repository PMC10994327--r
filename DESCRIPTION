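Package: hetg
Title: Simulation and Model-Based Analysis of Reciprocity Under Hidden
    Endowments
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how trustees reciprocate when the trust
    placed in them is ambiguous. Implements a hidden-endowment variant of
    the Trust Game: session design generation, synthetic trustee agents
    with known fairness norms and ambiguity-resolution strategies,
    grid-search maximum-likelihood fitting of an inequity-aversion
    reciprocity model, reverse inference of hidden endowments from
    observed returns, fitting and AIC comparison of ambiguity-resolution
    strategy models, strategy classification, and an end-to-end file-based
    pipeline with parameter-recovery diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
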