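Package: mrim
Title: Hybrid Machine-Learning and Rule-Based Triage of Emergency Microblogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies short social-media posts ("microblogs") produced during
    an emergency as useful or useless for rescue operations. Combines a TF-IDF
    plus linear support-vector-machine text classifier with an expert-weighted
    rule-based usefulness scorer over six judgment dimensions (attention, user
    history, sentiment, word count, exact address, contact information), and
    integrates the two by a recall-oriented union rule or a weighted score.
    Includes lexicon-based sentiment scoring with degree adverbs and negation,
    hierarchical address feature-word detection, contact-pattern extraction,
    grouped precision/recall/F evaluation, and a calibrated synthetic-corpus
    generator for end-to-end testing when real platform data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    Matrix,
    readr,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
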