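Package: hypermood
Title: Zero-Shot Personalized Mood Regression with Hypernetwork Adapters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying zero-shot personalization of sequence-encoder
    models for longitudinal depressed-mood monitoring. Provides a synthetic
    generator for ecological momentary assessment (EMA) speech studies
    (cohort with clinical questionnaires, session schedules, mood ratings
    and acoustic-functional features with configurable mood coupling), a
    small transformer encoder with adapter modules whose weights are
    generated per subject by metadata-conditioned hypernetworks, baseline
    feed-forward and fine-tuned-encoder models, deterministic training with
    AdamW and speaker-independent cross-validation, and an evaluation layer
    with per-speaker rank correlations, content-type breakdowns, and
    individual-fairness summaries (Gini index, winners/losers).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
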