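# Shared fixtures, all built in code.

# compact emotion lexicon (~60 terms) spanning the five working categories
mini_lexicon_df <- function() {
  data.frame(
    term = c("angry", "furious", "annoyed", "enraged", "resentful",
             "frustrated", "irritated", "livid",
             "afraid", "scared", "terrified", "anxious", "nervous",
             "worried", "fearful", "panicked",
             "sad", "unhappy", "depressed", "miserable", "heartbroken",
             "devastated", "lonely", "grieving",
             "happy", "glad", "joyful", "delighted", "excited", "proud",
             "relieved", "thrilled",
             "upset", "guilty", "ashamed", "jealous", "disgusted",
             "embarrassed",
             "surprised", "shocked", "numb"),
    variants = c("anger,angrily", "fury", "annoyance", "rage", "resentment",
                 "frustration", "irritation", "",
                 "", "scary", "terror,terrifying", "anxiety", "nervously",
                 "worry,worries", "fear,fears", "panic",
                 "sadness,sadly", "unhappiness", "depression", "misery",
                 "heartbreak", "devastating", "loneliness", "grief",
                 "happiness,happily", "gladly", "joy", "delight",
                 "excitement", "pride", "relief", "thrill",
                 "upsetting", "guilt", "shame", "jealousy", "disgust",
                 "embarrassment",
                 "surprise", "shock", ""),
    category = c(rep("anger", 8), rep("anxiety", 8), rep("sadness", 8),
                 rep("positive", 8), rep("negative", 6),
                 rep("other_affect", 3)),
    stringsAsFactors = FALSE)
}

mini_lexicon <- function() load_emotion_lexicon(mini_lexicon_df())

mini_stopwords <- function() {
  build_stopwords(c("i", "the", "a", "and", "to", "of", "it", "was", "my",
                    "like", "is", "me", "that", "would", "be", "very",
                    "i'd", "i'm", "don't", "so"))
}

mini_dic_text <- function() {
  c("%",
    "1\taffect", "2\tposemo", "3\tnegemo", "4\tanger",
    "5\tanxiety", "6\tsadness",
    "%",
    "hate*\t1\t3\t4", "angr*\t1\t3\t4", "furious\t1\t3\t4",
    "fear*\t1\t3\t5", "scar*\t1\t3\t5", "afraid\t1\t3\t5",
    "sad*\t1\t3\t6", "grie*\t1\t3\t6", "miser*\t1\t3\t6",
    "happ*\t1\t2", "joy*\t1\t2", "glad\t1\t2",
    "upset\t1\t3")
}

mini_dictionary <- function() load_category_dictionary(mini_dic_text())

# transcript with given named responses (others empty)
make_transcript <- function(id = "P1", group = "NT", ...) {
  dots <- list(...)
  resp <- stats::setNames(rep("", 17), as.character(1:17))
  for (nm in names(dots)) resp[[nm]] <- dots[[nm]]
  aprq_transcript(id, group, resp)
}

# fast low-volume generator profile for structural tests
small_profile <- function(seed = 1, n = 8, ...) {
  synthetic_config(seed = seed, n_per_group = n,
                   length_log_mean = c(ASD = 5.0, NT = 4.8),
                   length_log_sd = c(ASD = 0.5, NT = 0.5),
                   n_missing_tas = 1L, ...)
}

# equal-group null profile: every group-wise parameter identical
null_profile <- function(seed, n = 16) {
  synthetic_config(
    seed = seed, n_per_group = n,
    length_log_mean = c(ASD = 5.0, NT = 5.0),
    length_log_sd = c(ASD = 0.55, NT = 0.55),
    stopword_rate = c(ASD = 0.79, NT = 0.79),
    emotion_rate = c(ASD = 0.17, NT = 0.17),
    emotion_diversity = c(ASD = 1.7, NT = 1.7),
    zipf_exponent = c(ASD = 1.06, NT = 1.06),
    aq_group_mean = c(ASD = 5, NT = 5),
    tas_mean = c(ASD = 55, NT = 55),
    age_mean = c(ASD = 25, NT = 25), age_sd = c(ASD = 7, NT = 7),
    n_missing_tas = 0L)
}
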