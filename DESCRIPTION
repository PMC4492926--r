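Package: dxtrial
Title: Diagnostic Test Presentation Formats and Randomised Trial Analysis
Version: 0.1.0
Authors@R: person("dxtrial", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for Bayesian interpretation of diagnostic tests
    (likelihood ratios, post-test probabilities, predictive values) and for
    the four classic ways of presenting test accuracy to clinicians: a text
    summary, Fagan's nomogram, a probability-modifying plot and a natural
    frequency tree. Includes the answer-scoring rules and outcome analysis
    of a four-arm randomised trial of these formats (odds ratios with Wald
    intervals, chi-squared heterogeneity, logistic regression by iteratively
    reweighted least squares, two-proportion power calculations), a
    synthetic respondent-cohort generator so the full pipeline runs without
    external data, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
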