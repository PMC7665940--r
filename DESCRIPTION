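Package: textdx
Title: Diagnostic Accuracy Validation of Dictionary-Based Emotion Tagging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating dictionary-based (LIWC-style) emotion
    taggers against token-level human-coded reference annotations. Provides
    a lexicon engine (hierarchical emotion categories, word and stem entries,
    emoticons, context rules), alignment of machine tags with human codes,
    the full diagnostic-accuracy battery (sensitivity, specificity, positive
    and negative predictive values with Wilson or Wald intervals, F scores,
    pooled two-proportion tests with Bonferroni correction, Pearson
    correlations, Cohen's kappa, and the analytic dependence of PPV on
    prevalence), and a seeded synthetic-corpus generator with known ground
    truth for end-to-end calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    optparse,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
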