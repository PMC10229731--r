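test_that("tokenizer keeps contractions, folds case, drops punctuation", {
  expect_identical(tokenize("I'd run!"), c("i'd", "run"))
  expect_identical(tokenize(""), character())
  expect_identical(tokenize("Feel, FEEL feel."), c("feel", "feel", "feel"))
  expect_identical(tokenize("abc123 42 ok"), c("abc", "ok"))
  expect_identical(tokenize("it’s fine"), c("it's", "fine"))
  expect_identical(tokenize("'quoted'"), "quoted")
})

test_that("feature formulas on a hand-constructed response", {
  lex <- load_emotion_lexicon(data.frame(term = c("angry", "scared")))
  sw <- build_stopwords(c("i", "the"), character())
  t <- make_transcript("P1", "NT",
                       `1` = "I angry scared the angry house")
  f <- compute_features(t, lex, sw)
  expect_identical(f$raw_word_count, 6L)
  expect_identical(f$content_word_count, 4L)
  expect_identical(f$emotion_token_count, 3L)
  expect_identical(f$unique_emotion_word_count, 2L)
  expect_identical(f$non_emotion_word_count, 1L)
  expect_equal(f$ev_percent, 50)
  expect_equal(f$ttr_percent, 75)
})

test_that("all-stopword transcripts give undefined (not zero) ratios", {
  lex <- mini_lexicon()
  sw <- mini_stopwords()
  t <- make_transcript("P1", "ASD", `1` = "the i a", `2` = "and to")
  f <- compute_features(t, lex, sw)
  expect_identical(f$content_word_count, 0L)
  expect_true(is.na(f$ev_percent))
  expect_true(is.na(f$ttr_percent))
})

test_that("feature counts equal a brute-force membership scan on random text", {
  lex <- mini_lexicon()
  sw <- mini_stopwords()
  set.seed(42)
  pool <- c(lex$terms, sw, c("house", "tree", "run", "walk", "green"))
  for (rep in 1:5) {
    toks <- sample(pool, 200, replace = TRUE)
    t <- make_transcript("P", "NT", `3` = paste(toks, collapse = " "))
    f <- compute_features(t, lex, sw)
    content <- toks[!(toks %in% sw)]
    emo <- vapply(content, function(w) w %in% lex$terms, TRUE)
    expect_identical(f$raw_word_count, length(toks))
    expect_identical(f$content_word_count, length(content))
    expect_identical(f$emotion_token_count, sum(emo))
    expect_identical(f$unique_emotion_word_count,
                     length(unique(content[emo])))
    expect_identical(f$distinct_word_count, length(unique(content)))
  }
})

test_that("conservation and ordering invariants hold on fuzzed transcripts", {
  lex <- mini_lexicon()
  sw <- mini_stopwords()
  set.seed(7)
  pool <- c(lex$terms, sw, "xq", "zz", "house", "tree")
  for (rep in 1:20) {
    n_items <- sample(1:17, 1)
    resp <- lapply(seq_len(n_items), function(i) {
      paste(sample(pool, sample(0:40, 1), replace = TRUE), collapse = " ")
    })
    t <- aprq_transcript("P", "ASD",
                         stats::setNames(resp, sample(1:17, n_items)))
    f <- compute_features(t, lex, sw)
    expect_identical(f$emotion_token_count + f$non_emotion_word_count,
                     f$content_word_count)
    expect_lte(f$unique_emotion_word_count, f$distinct_word_count)
    expect_lte(f$distinct_word_count, f$content_word_count)
    expect_lte(f$content_word_count, f$raw_word_count)
    if (f$content_word_count > 0) {
      expect_lte(f$ev_percent, f$ttr_percent)
      expect_lte(f$ttr_percent, 100)
      expect_gte(f$ev_percent, 0)
    }
  }
})

test_that("adding an emotion token never decreases the emotion count", {
  lex <- mini_lexicon()
  sw <- mini_stopwords()
  t1 <- make_transcript("P", "NT", `1` = "the house was big")
  t2 <- make_transcript("P", "NT", `1` = "the house was big angry")
  f1 <- compute_features(t1, lex, sw)
  f2 <- compute_features(t2, lex, sw)
  expect_gte(f2$emotion_token_count, f1$emotion_token_count)
})

test_that("identical input yields identical features (determinism)", {
  lex <- mini_lexicon()
  sw <- mini_stopwords()
  t <- make_transcript("P", "NT", `1` = "I was so angry and scared",
                       `5` = "sad happy sad")
  expect_identical(compute_features(t, lex, sw),
                   compute_features(t, lex, sw))
})

test_that("category percentages: overlap, zero-match and empty input", {
  d <- mini_dictionary()
  toks <- c("hate", "happy", rep("tree", 8))
  pct <- category_percentages(toks, d)
  expect_equal(unname(pct["anger"]), 10)
  expect_equal(unname(pct["posemo"]), 10)
  expect_equal(unname(pct["affect"]), 20)  # overlap: both matches are affect
  expect_true(all(category_percentages(c("tree", "rock"), d) == 0))
  expect_true(all(is.na(category_percentages(character(), d))))
  # a token in three categories contributes to all three percentages
  pct2 <- category_percentages(c("furious", rep("x", 4)), d)
  expect_equal(unname(pct2[c("affect", "negemo", "anger")]), rep(20, 3))
})

test_that("feel bigram views follow the three-stage filter", {
  lex <- mini_lexicon()
  sw <- mini_stopwords()
  t <- make_transcript("P", "NT", `1` = "I feel like I'd feel sad")
  v <- extract_feel_bigrams(t, sw, lex)
  expect_identical(v$all$second, c("like", "sad"))
  expect_identical(v$content$second, "sad")
  expect_identical(nrow(v$residual), 0L)

  t2 <- make_transcript("P", "NT", `1` = "I feel hungry")
  v2 <- extract_feel_bigrams(t2, sw, lex)
  expect_identical(v2$residual$second, "hungry")

  t3 <- make_transcript("P", "NT", `1` = "nothing here")
  v3 <- extract_feel_bigrams(t3, sw, lex)
  expect_identical(vapply(v3, nrow, 0L), c(all = 0L, content = 0L,
                                           residual = 0L))
})

test_that("bigram filters are nested on fuzzed input", {
  lex <- mini_lexicon()
  sw <- mini_stopwords()
  set.seed(11)
  pool <- c("feel", "feels", "feeling", lex$terms[1:10], sw[1:5], "hungry",
            "sick", "tree")
  for (rep in 1:10) {
    t <- make_transcript("P", "ASD",
                         `2` = paste(sample(pool, 30, replace = TRUE),
                                     collapse = " "))
    v <- extract_feel_bigrams(t, sw, lex)
    key <- function(d) paste(d$item_id, seq_len(nrow(d)))
    expect_lte(nrow(v$content), nrow(v$all))
    expect_lte(nrow(v$residual), nrow(v$content))
    expect_true(all(v$content$second %in% v$all$second))
    expect_true(all(v$residual$second %in% v$content$second))
    expect_true(all(v$all$first %in% c("feel", "feels", "feeling")))
  }
})

test_that("transcript readers and writers round-trip both dialects", {
  coh <- generate_cohort(small_profile(seed = 3, n = 3))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_transcripts_jsonl(coh$transcripts, jl)
  back <- read_transcripts_jsonl(jl)
  expect_identical(lapply(back, unclass),
                   lapply(unname(coh$transcripts), unclass))
  cs <- withr::local_tempfile(fileext = ".csv")
  write_transcripts_csv(coh$transcripts, cs)
  back2 <- read_transcripts_csv(cs)
  expect_identical(lapply(unname(back2), `[[`, "responses"),
                   lapply(unname(coh$transcripts), `[[`, "responses"))
})
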