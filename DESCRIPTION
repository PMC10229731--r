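Package: aprqtext
Title: Emotional Language Analysis of APRQ Interview Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing emotional language in transcripts of the
    Alexithymia Provoked Response Questionnaire (APRQ), a 17-item structured
    interview of emotion-provoking scenarios. Provides lexicon-based emotion
    scoring with a configurable affect lexicon and LIWC-dialect category
    dictionaries, per-participant linguistic features (emotion word counts,
    Emotion Vocabulary, type/token ratio, category percentages, "feel"
    bigrams), questionnaire scoring for the TAS-20 and AQ-10, provocation
    congruence analysis, a statistical battery (Wilcoxon rank-sum with
    Vargha-Delaney A, Spearman and partial correlations, Welch t, chi-square,
    logistic regression with Hosmer-Lemeshow, Box-Tidwell, VIF and Cook's
    distance diagnostics), and a calibrated synthetic cohort generator so the
    full pipeline can be exercised and validated without access to clinical
    interview data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
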