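Package: lsnb
Title: Loosely Symmetric Naive Bayes Text Classification
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Binary text classification with the loosely symmetric (LS)
    cognitive-bias model integrated into a Bernoulli naive Bayes classifier.
    Provides the LS association measure on 2x2 contingency tables together
    with classical comparators (conditional probability, delta-P, dual-factor
    heuristic), the LSNB and word-density-weighted eLSNB classifier variants,
    tokenization and vocabulary filtering for email-style corpora, loaders
    for SpamAssassin- and Ling-Spam-style directory layouts, a seeded
    synthetic corpus generator, and an experiment harness for biased
    small-sample training schedules with per-class accuracy and F-measure
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
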