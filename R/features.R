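#' Tokenize response text
#'
#' Deterministic bag-of-words tokenizer: the text is lowercased, typographic
#' apostrophes are normalised to `'`, and maximal runs of letters with
#' internal apostrophes are extracted. Contractions are kept as single
#' tokens (`"I'd run!"` tokenizes to `c("i'd", "run")`); punctuation and
#' digits are discarded. The token definition is centralized here so every
#' count in the package is reproducible.
#'
#' @param text Character scalar (or vector; a vector yields a list).
#' @return Character vector of tokens (a list of such vectors for vector
#'   input). Empty text gives `character(0)`.
#' @export
tokenize <- function(text) {
  tk <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    x <- tolower(chartr("’", "'", x))
    m <- gregexpr("[a-z]+(?:'[a-z]+)*", x, perl = TRUE)[[1L]]
    if (m[1L] == -1L) character() else
      substring(x, m, m + attr(m, "match.length") - 1L)
  }
  if (length(text) == 1L) tk(text) else lapply(text, tk)
}

# content tokens (stopwords removed) for one transcript, per item
content_tokens_by_item <- function(transcript, stopwords) {
  toks <- lapply(transcript$responses, tokenize)
  lapply(toks, function(tt) tt[!(tt %in% stopwords)])
}

#' Per-participant linguistic features
#'
#' Computes the full feature vector for one transcript over the concatenation
#' of its item responses: raw and stopword-filtered token counts, distinct
#' counts, emotion/non-emotion splits, Emotion Vocabulary (EV) and type/token
#' ratio (TTR), and (if a dictionary is supplied) category percentages.
#'
#' EV is the number of distinct emotion types as a percentage of the content
#' word count; TTR is the number of distinct content types as a percentage of
#' the content word count. Emotion words are retained in both denominators:
#' for some respondents emotion words are a large share of the response, and
#' removing them would distort the diversity measures. Both are reported on
#' a 0-100 scale. When a transcript has no content tokens the ratios are
#' undefined and returned as `NA`, never as 0.
#'
#' @param transcript An [aprq_transcript].
#' @param lexicon An `emotion_lexicon` (nonempty).
#' @param stopwords Character vector of stopwords (nonempty).
#' @param dictionary Optional `category_dictionary`; adds one
#'   `pct_<category>` column per category (percentages of content tokens;
#'   categories may overlap, e.g. `affect` contains `anger`).
#' @return A one-row data frame with columns `participant_id`, `group`,
#'   `raw_word_count`, `content_word_count`, `distinct_word_count`,
#'   `emotion_token_count`, `unique_emotion_word_count`,
#'   `non_emotion_word_count`, `ev_percent`, `ttr_percent`, and optional
#'   category percentage columns.
#' @export
compute_features <- function(transcript, lexicon, stopwords,
                             dictionary = NULL) {
  stopifnot(inherits(transcript, "aprq_transcript"),
            inherits(lexicon, "emotion_lexicon"))
  if (!length(stopwords)) stop("stopword list is empty", call. = FALSE)
  raw <- unlist(lapply(transcript$responses, tokenize), use.names = FALSE)
  content <- raw[!(raw %in% stopwords)]
  n <- length(content)
  emo <- is_emotion_word(content, lexicon)
  n_emo <- sum(emo)
  uniq_emo <- length(unique(content[emo]))
  distinct <- length(unique(content))

  out <- data.frame(
    participant_id = transcript$participant_id,
    group = transcript$group,
    raw_word_count = length(raw),
    content_word_count = n,
    distinct_word_count = distinct,
    emotion_token_count = n_emo,
    unique_emotion_word_count = uniq_emo,
    non_emotion_word_count = n - n_emo,
    ev_percent = if (n > 0L) 100 * uniq_emo / n else NA_real_,
    ttr_percent = if (n > 0L) 100 * distinct / n else NA_real_,
    stringsAsFactors = FALSE)

  if (!is.null(dictionary)) {
    pct <- category_percentages(content, dictionary)
    for (nm in names(pct)) out[[paste0("pct_", nm)]] <- pct[[nm]]
  }
  out
}

#' Feature table for a whole cohort
#'
#' @param cohort An [aprq_cohort] or list of [aprq_transcript] objects.
#' @inheritParams compute_features
#' @return Data frame, one row per participant (see [compute_features()]).
#' @export
feature_table <- function(cohort, lexicon, stopwords, dictionary = NULL) {
  transcripts <- if (inherits(cohort, "aprq_cohort")) cohort$transcripts
                 else cohort
  do.call(rbind, lapply(transcripts, compute_features, lexicon = lexicon,
                        stopwords = stopwords, dictionary = dictionary))
}

#' Category percentages for a token list
#'
#' For each dictionary category, 100 x (tokens matching the category) /
#' (number of tokens). Categories may overlap, so percentages need not sum
#' to 100. An empty token list yields `NA` for every category (undefined,
#' not zero).
#'
#' @param tokens Character vector of (content) tokens.
#' @param dictionary A `category_dictionary`.
#' @return Named numeric vector of percentages, one per category.
#' @export
category_percentages <- function(tokens, dictionary) {
  stopifnot(inherits(dictionary, "category_dictionary"))
  cats <- unname(dictionary$category_names)
  if (!length(tokens)) {
    return(stats::setNames(rep(NA_real_, length(cats)), cats))
  }
  m <- category_token_matrix(tokens, dictionary)
  stats::setNames(100 * colSums(m) / length(tokens), cats)
}

#' Extract "feel" bigrams
#'
#' Scans each item response for adjacent token pairs whose first token is
#' `feel`, `feels` or `feeling`, the syntactic frame a pure bag-of-words
#' count can miss ("feel awful", "not happy"). Three nested views are
#' returned: all such bigrams; those whose second token is not a stopword;
#' and the residual view with lexicon-matching second tokens also removed —
#' the "feel --" constructions that name something other than a recognised
#' emotion term (e.g. "feel hungry", "feel sick").
#'
#' @param transcript An [aprq_transcript].
#' @param stopwords Character vector of stopwords.
#' @param lexicon An `emotion_lexicon`.
#' @return List of three data frames (`all`, `content`, `residual`), each
#'   with columns `participant_id`, `item_id`, `first`, `second`, satisfying
#'   `residual` subset-of `content` subset-of `all`.
#' @export
extract_feel_bigrams <- function(transcript, stopwords, lexicon) {
  stopifnot(inherits(transcript, "aprq_transcript"))
  feel_forms <- c("feel", "feels", "feeling")
  rows <- lapply(names(transcript$responses), function(item) {
    tt <- tokenize(transcript$responses[[item]])
    if (length(tt) < 2L) return(NULL)
    i <- which(tt[-length(tt)] %in% feel_forms)
    if (!length(i)) return(NULL)
    data.frame(participant_id = transcript$participant_id,
               item_id = as.integer(item),
               first = tt[i], second = tt[i + 1L],
               stringsAsFactors = FALSE)
  })
  all_bg <- do.call(rbind, rows)
  if (is.null(all_bg)) {
    all_bg <- data.frame(participant_id = character(), item_id = integer(),
                         first = character(), second = character(),
                         stringsAsFactors = FALSE)
  }
  content <- all_bg[!(all_bg$second %in% stopwords), , drop = FALSE]
  residual <- content[!is_emotion_word(content$second, lexicon), ,
                      drop = FALSE]
  list(all = all_bg, content = content, residual = residual)
}

#' Cohort-level "feel" bigram summary
#'
#' @param cohort An [aprq_cohort] or list of transcripts.
#' @inheritParams extract_feel_bigrams
#' @return List with the three pooled bigram data frames plus a `counts`
#'   vector and a frequency table of residual second tokens.
#' @export
feel_bigram_summary <- function(cohort, stopwords, lexicon) {
  transcripts <- if (inherits(cohort, "aprq_cohort")) cohort$transcripts
                 else cohort
  views <- lapply(transcripts, extract_feel_bigrams, stopwords = stopwords,
                  lexicon = lexicon)
  pool <- function(nm) do.call(rbind, lapply(views, `[[`, nm))
  all_bg <- pool("all"); content <- pool("content"); residual <- pool("residual")
  list(all = all_bg, content = content, residual = residual,
       counts = c(all = nrow(all_bg), content = nrow(content),
                  residual = nrow(residual)),
       residual_second = sort(table(residual$second), decreasing = TRUE))
}
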