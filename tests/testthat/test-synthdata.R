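test_that("configs are validated and group vectors recycled", {
  cfg <- synthetic_config(emotion_rate = 0.2)
  expect_equal(unname(cfg$emotion_rate), c(0.2, 0.2))
  expect_error(synthetic_config(n_per_group = 1))
  expect_error(synthetic_config(emotion_rate = c(ASD = 1.2, NT = 0.1)))
  expect_error(synthetic_config(incongruence_prob = -0.1))
  expect_error(synthetic_config(length_log_sd = c(ASD = 0, NT = 0.5)))
  expect_error(synthetic_config(emotion_rate = c(asd = 0.1, nt = 0.2)),
               "named")
})

test_that("same config and seed give byte-identical JSONL output", {
  cfg <- small_profile(seed = 8, n = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- readLines(file.path(d1, "transcripts.jsonl"))
  f2 <- readLines(file.path(d2, "transcripts.jsonl"))
  expect_identical(f1, f2)
  expect_identical(readLines(file.path(d1, "instruments.csv")),
                   readLines(file.path(d2, "instruments.csv")))
  # and a different seed gives different text
  d3 <- withr::local_tempdir()
  write_cohort(generate_cohort(small_profile(seed = 9, n = 4)), d3)
  expect_false(identical(f1, readLines(file.path(d3, "transcripts.jsonl"))))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(generate_cohort(small_profile(seed = 5, n = 3)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("zero emotion rate yields zero emotion tokens and EV everywhere", {
  cfg <- small_profile(seed = 11, n = 5, emotion_rate = c(ASD = 0, NT = 0),
                       feel_bigram_rate = 0)
  coh <- generate_cohort(cfg)
  ft <- feature_table(coh, default_emotion_lexicon(), default_stopwords())
  expect_true(all(ft$emotion_token_count == 0))
  expect_true(all(ft$ev_percent == 0, na.rm = TRUE))
  expect_true(all(coh$ground_truth$emotion_token_count == 0))
})

test_that("a lexicon missing a required category is a configuration error", {
  lex <- load_emotion_lexicon(data.frame(term = c("angry", "sad"),
                                         category = c("anger", "sadness")))
  expect_error(generate_cohort(small_profile(seed = 1, n = 3), lex),
               "sublexicon empty")
})

test_that("ground truth aligns with emitted transcripts and feature counts", {
  coh <- generate_cohort(small_profile(seed = 12, n = 6))
  gt <- coh$ground_truth
  ids <- vapply(coh$transcripts, `[[`, "", "participant_id")
  expect_identical(gt$participant_id, ids)
  expect_identical(gt$group, vapply(coh$transcripts, `[[`, "", "group"))
  ft <- feature_table(coh, default_emotion_lexicon(), default_stopwords())
  # emitted emotion tokens >= generator count is impossible; equality up to
  # feel-bigram injections which may add lexicon words
  expect_true(all(ft$emotion_token_count >= gt$emotion_token_count))
})

test_that("equal-group configs give null-calibrated group differences", {
  As <- vapply(1:25, function(r) {
    coh <- generate_cohort(null_profile(seed = 300 + r, n = 12))
    ft <- feature_table(coh, default_emotion_lexicon(), default_stopwords())
    vda_effect_size(ft$emotion_token_count[ft$group == "ASD"],
                    ft$emotion_token_count[ft$group == "NT"])$A
  }, 0)
  expect_lt(abs(mean(As) - 0.5), 0.06)
})

test_that("a configured 2x emotion-rate ratio is recovered by measurement", {
  ratios <- vapply(1:40, function(r) {
    cfg <- synthetic_config(
      seed = 500 + r, n_per_group = 32,
      length_log_mean = c(ASD = 5.3, NT = 5.3),
      length_log_sd = c(ASD = 0.5, NT = 0.5),
      stopword_rate = c(ASD = 0.7, NT = 0.7),
      emotion_rate = c(ASD = 0.1, NT = 0.2),
      emotion_diversity = c(ASD = 1.2, NT = 1.2),
      zipf_exponent = c(ASD = 1.05, NT = 1.05),
      trait_emotion_coef = 0, feel_bigram_rate = 0, n_missing_tas = 0L)
    coh <- generate_cohort(cfg)
    ft <- feature_table(coh, default_emotion_lexicon(), default_stopwords())
    prop <- ft$emotion_token_count / ft$content_word_count
    mean(prop[ft$group == "NT"]) / mean(prop[ft$group == "ASD"])
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("AQ-10 totals track expressiveness with the configured association", {
  rhos <- vapply(1:15, function(r) {
    coh <- generate_cohort(default_paper_profile(seed = 700 + r))
    ft <- feature_table(coh, default_emotion_lexicon(), default_stopwords())
    sc <- score_instruments(coh, default_emotion_lexicon())
    spearman_cor(sc$aq10_total,
                 ft$emotion_token_count / ft$content_word_count)$rho
  }, 0)
  expect_lt(abs(mean(rhos) - (-0.35)), 0.15)
  expect_true(all(rhos < 0))
})

test_that("the paper profile approximates its calibration anchors", {
  stats <- vapply(1:10, function(r) {
    coh <- generate_cohort(default_paper_profile(seed = 900 + r))
    ft <- feature_table(coh, default_emotion_lexicon(), default_stopwords())
    asd <- ft$group == "ASD"
    c(mean(ft$raw_word_count[asd]), mean(ft$raw_word_count[!asd]),
      mean(ft$emotion_token_count[asd]), mean(ft$emotion_token_count[!asd]),
      mean(ft$non_emotion_word_count[asd]),
      mean(ft$non_emotion_word_count[!asd]))
  }, numeric(6))
  m <- rowMeans(stats)
  anchors <- c(1066, 606, 24.09, 28.66, 184.62, 104.63)
  expect_true(all(abs(m - anchors) / anchors < 0.25))
})

test_that("cohort round-trips through the on-disk dialects", {
  coh <- generate_cohort(small_profile(seed = 13, n = 4))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(lapply(back$transcripts, unclass),
                   lapply(coh$transcripts, unclass))
  expect_identical(back$instruments$participant_id,
                   coh$instruments$participant_id)
  expect_equal(back$instruments$tas_1, coh$instruments$tas_1)
})
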