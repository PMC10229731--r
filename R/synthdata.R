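#' Synthetic cohort configuration
#'
#' Parameters of the synthetic transcript-and-questionnaire generator. The
#' defaults constitute the paper-calibrated profile (see
#' [default_paper_profile()]): group-specific interview lengths are
#' log-normal (linguistic counts are heavily right-skewed), a fixed share of
#' tokens are stopwords/fillers, content tokens are a mixture of
#' Zipf-distributed neutral words and emotion words drawn from the
#' provocation-congruent sublexicon, and questionnaire totals are generated
#' from a latent expressiveness trait so that instrument scorers and
#' correlation analyses are exercised end-to-end.
#'
#' Group-wise parameters are length-2 vectors named `ASD`/`NT`.
#'
#' @param n_per_group Participants per group (>= 2).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param length_log_mean,length_log_sd Log-normal parameters of the raw
#'   (pre-stopword-removal) token count per interview.
#' @param stopword_rate Probability a raw token is a stopword/filler.
#' @param emotion_rate Expected share of content tokens that are emotion
#'   words for an interview of reference (group-expected) content length.
#' @param emotion_length_scaling Exponent `s` in the sublinear growth of
#'   expected emotion tokens with content length (`count ~ length^s`);
#'   values below 1 mean verbose interviews dilute their emotion-word rate,
#'   which matches the much lower dispersion of emotion counts than of
#'   total counts in interview data.
#' @param emotion_diversity Zipf exponent over each emotion sublexicon
#'   (0 = uniform use of the sublexicon; larger = more repetition of a few
#'   favourite terms).
#' @param incongruence_prob Probability an emitted emotion token is drawn
#'   from a non-matching core category instead of the item's congruent one.
#' @param trait_emotion_coef Effect of the latent expressiveness trait
#'   (standard normal per participant) on the log emotion rate.
#' @param trait_noise_sd SD of the noise linking the trait to the AQ-10
#'   total (larger = weaker AQ-10/emotion-language association).
#' @param vocabulary_size,zipf_exponent Size of the neutral content
#'   vocabulary and the (group-wise) Zipf exponent governing how
#'   concentrated its use is; the exponent controls each group's distinct
#'   word count and hence its type/token ratio.
#' @param feel_bigram_rate Probability a response receives an injected
#'   "feel <word>" bigram.
#' @param aq_group_mean Latent AQ-10 group means (0-10 scale).
#' @param aq_trait_slope Drop in latent AQ-10 per SD of expressiveness.
#' @param tas_mean,tas_sd TAS-20 total distribution per group.
#' @param tas_trait_slope Effect of expressiveness on the TAS-20 total
#'   (default 0: the TAS-20 is generated independent of emotion-language
#'   use within group, reflecting the absence of an established
#'   population-level association).
#' @param age_mean,age_sd Age distribution per group.
#' @param n_missing_tas Number of NT participants whose TAS-20 is missing
#'   (instrument non-completion).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_group = 32L,
                             seed = 1L,
                             length_log_mean = c(ASD = 6.714, NT = 6.194),
                             length_log_sd = c(ASD = 0.719, NT = 0.653),
                             stopword_rate = c(ASD = 0.804, NT = 0.779),
                             emotion_rate = c(ASD = 0.118, NT = 0.215),
                             emotion_length_scaling = 0.5,
                             emotion_diversity = c(ASD = 1.6, NT = 1.8),
                             incongruence_prob = 0.25,
                             trait_emotion_coef = 0.15,
                             trait_noise_sd = 3.0,
                             vocabulary_size = 5000L,
                             zipf_exponent = c(ASD = 1.05, NT = 1.07),
                             feel_bigram_rate = 0.18,
                             aq_group_mean = c(ASD = 7.5, NT = 3.0),
                             aq_trait_slope = 1.0,
                             tas_mean = c(ASD = 62, NT = 52),
                             tas_sd = c(ASD = 9, NT = 9),
                             tas_trait_slope = 0,
                             age_mean = c(ASD = 26.5, NT = 24.5),
                             age_sd = c(ASD = 8, NT = 6),
                             n_missing_tas = 1L) {
  grpvec <- function(x, nm) {
    if (length(x) == 1L) x <- c(ASD = unname(x), NT = unname(x))
    if (!all(c("ASD", "NT") %in% names(x))) {
      stop("'", nm, "' must be named with ASD and NT", call. = FALSE)
    }
    x[c("ASD", "NT")]
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group), seed = as.integer(seed),
    length_log_mean = grpvec(length_log_mean, "length_log_mean"),
    length_log_sd = grpvec(length_log_sd, "length_log_sd"),
    stopword_rate = grpvec(stopword_rate, "stopword_rate"),
    emotion_rate = grpvec(emotion_rate, "emotion_rate"),
    emotion_length_scaling = emotion_length_scaling,
    emotion_diversity = grpvec(emotion_diversity, "emotion_diversity"),
    incongruence_prob = incongruence_prob,
    trait_emotion_coef = trait_emotion_coef,
    trait_noise_sd = trait_noise_sd,
    vocabulary_size = as.integer(vocabulary_size),
    zipf_exponent = grpvec(zipf_exponent, "zipf_exponent"),
    feel_bigram_rate = feel_bigram_rate,
    aq_group_mean = grpvec(aq_group_mean, "aq_group_mean"),
    aq_trait_slope = aq_trait_slope,
    tas_mean = grpvec(tas_mean, "tas_mean"),
    tas_sd = grpvec(tas_sd, "tas_sd"),
    tas_trait_slope = tas_trait_slope,
    age_mean = grpvec(age_mean, "age_mean"),
    age_sd = grpvec(age_sd, "age_sd"),
    n_missing_tas = as.integer(n_missing_tas))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 2L,
            all(cfg$stopword_rate >= 0 & cfg$stopword_rate <= 1),
            all(cfg$emotion_rate >= 0 & cfg$emotion_rate <= 1),
            cfg$incongruence_prob >= 0, cfg$incongruence_prob <= 1,
            cfg$feel_bigram_rate >= 0, cfg$feel_bigram_rate <= 1,
            all(cfg$length_log_sd > 0), all(cfg$tas_sd > 0),
            all(cfg$age_sd > 0), cfg$trait_noise_sd >= 0,
            cfg$vocabulary_size >= 10L, all(cfg$zipf_exponent >= 0),
            all(cfg$emotion_diversity >= 0),
            cfg$emotion_length_scaling > 0,
            cfg$n_missing_tas >= 0L, cfg$n_missing_tas < cfg$n_per_group)
  invisible(cfg)
}

#' Paper-calibrated generator profile
#'
#' The default [synthetic_config()], whose expected cohort summaries
#' approximate the published group anchors the generator emulates: ASD
#' interviews longer but with fewer emotion words (raw word count around
#' 1066 vs 606; post-stopword content around 209 vs 134; emotion word count
#' around 24 vs 29; non-emotion count around 185 vs 105), lower Emotion
#' Vocabulary in the ASD group with a near-null type/token ratio
#' difference, a majority of the ASD group above the TAS-20 cut-off, and a
#' negative AQ-10 / emotion-word-proportion association of roughly -0.35.
#'
#' @param seed Integer seed.
#' @param n_per_group Participants per group.
#' @return A `synthetic_config`.
#' @export
default_paper_profile <- function(seed = 1L, n_per_group = 32L) {
  synthetic_config(seed = seed, n_per_group = n_per_group)
}

# deterministic letter-only word for neutral vocabulary index k
neutral_word <- function(k) {
  vapply(k, function(i) {
    i <- i - 1L
    s <- ""
    repeat {
      s <- paste0(letters[i %% 26L + 1L], s)
      i <- i %/% 26L
      if (i == 0L) break
      i <- i - 1L
    }
    paste0("x", s)
  }, "")
}

# internal pool of stopword tokens the generator emits; all of these are in
# the packaged stopword list (or are the default fillers)
STOPWORD_EMISSION_POOL <- c(
  "the", "i", "a", "and", "to", "of", "it", "that", "was", "my", "in",
  "is", "you", "me", "be", "would", "have", "so", "but", "they", "he",
  "she", "we", "them", "this", "what", "if", "then", "there", "just",
  "very", "i'd", "i'm", "it's", "don't", "hmm", "ahm", "ehm")

#' Generate a synthetic APRQ cohort
#'
#' Draws a full two-group cohort — transcripts, instrument responses and
#' generating ground truth — from a [synthetic_config()]. Per participant:
#' a latent expressiveness trait is drawn; the raw interview length is
#' log-normal and split across the 17 items; each item's tokens are a
#' mixture of stopwords/fillers, Zipf-distributed neutral words, and
#' emotion words drawn from the item's provocation-congruent sublexicon
#' (switched to an incongruent core category with probability
#' `incongruence_prob`; unclassified items draw from all categories);
#' "feel <word>" bigrams are injected at a configurable rate. AQ-10 totals
#' are generated to covary negatively with expressiveness, TAS-20 totals
#' with a group shift, and both are back-converted to item-level Likert
#' responses consistent with the total so the instrument scorers run on
#' realistic input.
#'
#' @param cfg A `synthetic_config`.
#' @param lexicon An `emotion_lexicon` supplying the emotion sublexicons
#'   (default: the packaged lexicon).
#' @return An [aprq_cohort] whose `ground_truth` data frame records, per
#'   participant, the latent trait, generating emotion rate and realized
#'   emotion token count.
#' @export
generate_cohort <- function(cfg, lexicon = default_emotion_lexicon()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(cfg$seed)

  core_cats <- c("anger", "anxiety", "sadness")
  all_cats <- c(core_cats, "positive", "negative")
  sublex <- lapply(stats::setNames(nm = all_cats), emotion_sublexicon,
                   lexicon = lexicon)
  empty <- names(sublex)[lengths(sublex) == 0L]
  if (length(empty)) {
    stop("emotion sublexicon empty for categor(ies): ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  sub_weights <- lapply(stats::setNames(nm = c("ASD", "NT")), function(g) {
    lapply(sublex, function(words) {
      w <- seq_along(words)^(-cfg$emotion_diversity[[g]])
      w / sum(w)
    })
  })
  zipf_w <- lapply(stats::setNames(nm = c("ASD", "NT")), function(g) {
    w <- seq_len(cfg$vocabulary_size)^(-cfg$zipf_exponent[[g]])
    w / sum(w)
  })
  stop_w <- seq_along(STOPWORD_EMISSION_POOL)^(-0.8)
  map <- provocation_map()
  feel_extras <- c("hungry", "sick", "dizzy", "weird", "odd", "strange",
                   "cold", "warm", "tired", "funny")

  gen_participant <- function(pid, g) {
    z <- stats::rnorm(1L)
    L_raw <- max(34L, round(stats::rlnorm(1L, cfg$length_log_mean[[g]],
                                          cfg$length_log_sd[[g]])))
    item_w <- stats::rgamma(17L, shape = 2, rate = 1)
    raw_j <- as.integer(stats::rmultinom(1L, L_raw, item_w))
    content_j <- stats::rbinom(17L, raw_j, 1 - cfg$stopword_rate[[g]])
    n_i <- sum(content_j)
    n_ref <- (1 - cfg$stopword_rate[[g]]) *
      exp(cfg$length_log_mean[[g]] + cfg$length_log_sd[[g]]^2 / 2)
    rho <- cfg$emotion_rate[[g]] *
      (max(n_i, 1L) / n_ref)^(cfg$emotion_length_scaling - 1) *
      exp(cfg$trait_emotion_coef * z - cfg$trait_emotion_coef^2 / 2)
    rho <- min(max(rho, 0), 0.9)
    emo_j <- stats::rbinom(17L, content_j, rho)

    responses <- character(17L)
    for (j in 1:17) {
      n_stop <- raw_j[j] - content_j[j]
      n_emo <- emo_j[j]
      n_neut <- content_j[j] - n_emo
      toks <- character(0)
      if (n_stop > 0L) {
        toks <- c(toks, sample(STOPWORD_EMISSION_POOL, n_stop,
                               replace = TRUE, prob = stop_w))
      }
      if (n_neut > 0L) {
        toks <- c(toks, neutral_word(sample.int(cfg$vocabulary_size, n_neut,
                                                replace = TRUE,
                                                prob = zipf_w[[g]])))
      }
      if (n_emo > 0L) {
        prov <- map[[as.character(j)]]
        cats <- vapply(seq_len(n_emo), function(k) {
          if (prov == "unclassified") {
            sample(all_cats, 1L)
          } else if (stats::runif(1L) < cfg$incongruence_prob) {
            sample(setdiff(core_cats, prov), 1L)
          } else prov
        }, "")
        toks <- c(toks, vapply(cats, function(cc) {
          sample(sublex[[cc]], 1L, prob = sub_weights[[g]][[cc]])
        }, ""))
      }
      if (length(toks)) toks <- sample(toks)
      if (stats::runif(1L) < cfg$feel_bigram_rate) {
        first <- sample(c("feel", "feels", "feeling"), 1L,
                        prob = c(0.7, 0.1, 0.2))
        u <- stats::runif(1L)
        second <- if (u < 0.5) {
          sample(STOPWORD_EMISSION_POOL[1:20], 1L)
        } else if (u < 0.8) {
          prov <- map[[as.character(j)]]
          cc <- if (prov == "unclassified") sample(all_cats, 1L) else prov
          sample(sublex[[cc]], 1L, prob = sub_weights[[g]][[cc]])
        } else sample(feel_extras, 1L)
        pos <- sample.int(length(toks) + 1L, 1L) - 1L
        toks <- append(toks, c(first, second), after = pos)
      }
      responses[j] <- paste(toks, collapse = " ")
    }

    aq_latent <- cfg$aq_group_mean[[g]] - cfg$aq_trait_slope * z +
      stats::rnorm(1L, 0, cfg$trait_noise_sd)
    aq_total <- min(max(round(aq_latent), 0L), 10L)
    tas_total <- min(max(round(cfg$tas_mean[[g]] +
                                 cfg$tas_sd[[g]] * stats::rnorm(1L) +
                                 cfg$tas_trait_slope * z), 20L), 100L)
    age <- max(18L, round(stats::rnorm(1L, cfg$age_mean[[g]],
                                       cfg$age_sd[[g]])))
    list(
      transcript = aprq_transcript(pid, g,
                                   stats::setNames(responses,
                                                   as.character(1:17))),
      aq_items = aq10_items_from_total(aq_total),
      tas_items = tas20_items_from_total(tas_total),
      age = age,
      truth = data.frame(participant_id = pid, group = g,
                         latent_expressiveness = z,
                         emotion_rate = rho,
                         raw_length = L_raw,
                         content_target = n_i,
                         emotion_token_count = sum(emo_j),
                         aq10_total_target = aq_total,
                         tas20_total_target = tas_total,
                         stringsAsFactors = FALSE))
  }

  ids <- c(sprintf("ASD%02d", seq_len(cfg$n_per_group)),
           sprintf("NT%02d", seq_len(cfg$n_per_group)))
  groups <- rep(c("ASD", "NT"), each = cfg$n_per_group)
  parts <- unname(Map(gen_participant, ids, groups))

  miss <- if (cfg$n_missing_tas > 0L) {
    cfg$n_per_group + sample.int(cfg$n_per_group, cfg$n_missing_tas)
  } else integer()

  inst <- do.call(rbind, lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    tas <- if (i %in% miss) rep(NA_integer_, 20L) else p$tas_items
    row <- data.frame(participant_id = ids[i], age = p$age,
                      stringsAsFactors = FALSE)
    row[paste0("tas_", 1:20)] <- as.list(tas)
    row[paste0("aq_", 1:10)] <- as.list(p$aq_items)
    row
  }))

  aprq_cohort(transcripts = lapply(parts, `[[`, "transcript"),
              instruments = inst,
              ground_truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}

# random 20-item TAS-20 raw response pattern whose scored total equals
# `total` (scored scale: reverse-keyed items already transformed)
tas20_items_from_total <- function(total,
                                   reverse_items = c(4L, 5L, 10L, 18L, 19L)) {
  total <- min(max(total, 20L), 100L)
  s <- rep(3L, 20L)
  delta <- total - 60L
  step <- if (delta > 0) 1L else -1L
  while (delta != 0L) {
    room <- if (step > 0) which(s < 5L) else which(s > 1L)
    k <- if (length(room) == 1L) room else sample(room, 1L)
    s[k] <- s[k] + step
    delta <- delta - step
  }
  raw <- s
  raw[reverse_items] <- 6L - s[reverse_items]
  raw
}

# random 10-item AQ-10 raw Likert pattern whose bimodal score equals `total`
aq10_items_from_total <- function(total, agree_keyed = c(1L, 7L, 8L, 10L)) {
  total <- min(max(total, 0L), 10L)
  scored <- logical(10L)
  if (total > 0L) scored[sample.int(10L, total)] <- TRUE
  keyed <- logical(10L)
  keyed[agree_keyed] <- TRUE
  # keyed side: agree (1,2) for agree-keyed items, disagree (3,4) otherwise
  on_agree_side <- scored == keyed
  ifelse(on_agree_side, sample(1:2, 10L, replace = TRUE),
         sample(3:4, 10L, replace = TRUE))
}

#' Write a cohort to disk
#'
#' Emits the exact file dialects the readers consume: `transcripts.jsonl`,
#' `instruments.csv` and (when present) `ground_truth.csv`.
#'
#' @param cohort An [aprq_cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aprq_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transcripts_jsonl(cohort$transcripts,
                          file.path(dir, "transcripts.jsonl"))
  if (!is.null(cohort$instruments)) {
    write_instruments_csv(cohort$instruments,
                          file.path(dir, "instruments.csv"))
  }
  if (!is.null(cohort$ground_truth)) {
    utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `transcripts.jsonl` and optionally
#'   `instruments.csv` / `ground_truth.csv`.
#' @return An [aprq_cohort].
#' @export
read_cohort <- function(dir) {
  tpath <- file.path(dir, "transcripts.jsonl")
  if (!file.exists(tpath)) stop("no transcripts.jsonl in ", dir,
                                call. = FALSE)
  ipath <- file.path(dir, "instruments.csv")
  gpath <- file.path(dir, "ground_truth.csv")
  aprq_cohort(
    transcripts = read_transcripts_jsonl(tpath),
    instruments = if (file.exists(ipath)) read_instruments_csv(ipath),
    ground_truth = if (file.exists(gpath))
      utils::read.csv(gpath, stringsAsFactors = FALSE))
}
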