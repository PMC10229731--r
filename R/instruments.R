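#' Score the TAS-20
#'
#' Total score of the 20-item Toronto Alexithymia Scale. Items are rated on
#' a five-point Likert scale (1-5); reverse-keyed items are transformed
#' `v -> 6 - v` before summing, so totals range 20-100. The conventional
#' alexithymia cut-off is a total of 61 or more. An out-of-range or missing
#' item marks the whole instrument missing (`NA`); items are never imputed.
#'
#' @param items Numeric vector of 20 raw item responses in 1..5.
#' @param reverse_items Indices of reverse-keyed items; defaults to the
#'   published standard set `{4, 5, 10, 18, 19}`.
#' @return List with `total` (20..100 or `NA`) and `alexithymic`
#'   (`total >= 61`, or `NA`).
#' @export
score_tas20 <- function(items, reverse_items = c(4L, 5L, 10L, 18L, 19L)) {
  items <- as.numeric(items)
  if (length(items) != 20L || anyNA(items) ||
      any(items < 1 | items > 5 | items != round(items))) {
    return(list(total = NA_integer_, alexithymic = NA))
  }
  scored <- items
  scored[reverse_items] <- 6 - scored[reverse_items]
  total <- as.integer(sum(scored))
  list(total = total, alexithymic = total >= 61L)
}

#' Score the AQ-10
#'
#' Bimodal scoring of the 10-item Autism Quotient screen. Each item is
#' answered on a four-point Likert scale (1 = definitely agree ... 4 =
#' definitely disagree); the two agree levels and the two disagree levels
#' are merged, and an item scores 1 when the response falls on its keyed
#' side (agree side for agree-keyed items, disagree side otherwise). Totals
#' range 0-10; six or more scores screen positive.
#'
#' @param items Numeric vector of 10 raw item responses in 1..4.
#' @param agree_keyed Indices of agree-keyed items. The default
#'   `{1, 7, 8, 10}` is the published key, shipped as configuration rather
#'   than hard-coded.
#' @return List with `total` (0..10 or `NA`) and `screen_positive`
#'   (`total >= 6`, or `NA`).
#' @export
score_aq10 <- function(items, agree_keyed = c(1L, 7L, 8L, 10L)) {
  items <- as.numeric(items)
  if (length(items) != 10L || anyNA(items) ||
      any(items < 1 | items > 4 | items != round(items))) {
    return(list(total = NA_integer_, screen_positive = NA))
  }
  agree_side <- items <= 2
  keyed <- logical(10L)
  keyed[agree_keyed] <- TRUE
  total <- as.integer(sum(agree_side == keyed))
  list(total = total, screen_positive = total >= 6L)
}

#' Automated APRQ scoring from transcripts
#'
#' The APRQ rates each of the 17 responses 0/1: 1 when the response
#' describes affect, 0 (alexithymic) when it describes only an intended
#' action, the situation, or physical sensations ("I'd run", "I'd fight").
#' This automated approximation of the human rating scores an item 1 iff at
#' least one content token of the response matches the emotion lexicon.
#' Tokens matching the lexicon are treated as affect regardless of context,
#' and physical-sensation or situation descriptions are only excluded
#' insofar as their words are absent from the lexicon — a stated validity
#' caveat of the automated rule relative to human rating. Items missing
#' from the transcript score 0 with a warning.
#'
#' @param transcript An [aprq_transcript] with at least one item.
#' @param lexicon An `emotion_lexicon`.
#' @param stopwords Optional stopword vector applied before matching
#'   (lexicon terms are content words, so this rarely changes scores).
#' @return List with `total` (0..17) and `items`, a named 0/1 integer vector
#'   over items 1..17.
#' @export
auto_score_aprq <- function(transcript, lexicon, stopwords = character()) {
  stopifnot(inherits(transcript, "aprq_transcript"),
            length(transcript$responses) >= 1L)
  item_ids <- as.character(1:17)
  missing <- setdiff(item_ids, names(transcript$responses))
  if (length(missing)) {
    warning("APRQ items missing from transcript (scored 0): ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  scores <- stats::setNames(integer(17L), item_ids)
  for (item in names(transcript$responses)) {
    tt <- tokenize(transcript$responses[[item]])
    tt <- tt[!(tt %in% stopwords)]
    scores[[item]] <- as.integer(any(is_emotion_word(tt, lexicon)))
  }
  list(total = as.integer(sum(scores)), items = scores)
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(totals))` for an
#' items-in-columns matrix. Undefined (NA, with a warning) when the totals
#' have zero variance.
#'
#' @param item_matrix Numeric matrix or data frame, participants x items
#'   (k >= 2, no missing cells).
#' @return Alpha (numeric scalar, possibly `NA`).
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  stopifnot(ncol(m) >= 2L)
  if (anyNA(m)) stop("item matrix must have no missing cells", call. = FALSE)
  k <- ncol(m)
  var_total <- stats::var(rowSums(m))
  if (var_total == 0) {
    warning("zero total-score variance; alpha undefined", call. = FALSE)
    return(NA_real_)
  }
  k / (k - 1) * (1 - sum(apply(m, 2L, stats::var)) / var_total)
}

#' Count and percentage satisfying a flag, within a group
#'
#' Reporting helper for statements of the form "18 of the participants or
#' 56.2% were in the alexithymic range". The percentage is rounded
#' half-to-even at one decimal (so 15.625 prints as 15.6 and 56.25 as 56.2),
#' matching conventional printed precision.
#'
#' @param flags Logical vector (one per group member; `NA`s are counted in
#'   the denominator unless `na.rm = TRUE`).
#' @param na.rm Drop `NA` flags before counting?
#' @return List with `count`, `n` and `percent` (1 decimal).
#' @export
group_proportion_summary <- function(flags, na.rm = FALSE) {
  flags <- as.logical(flags)
  if (na.rm) flags <- flags[!is.na(flags)]
  if (!length(flags)) stop("empty group", call. = FALSE)
  count <- sum(flags, na.rm = TRUE)
  list(count = count, n = length(flags),
       percent = round(100 * count / length(flags), 1L))
}

#' Score all instruments for a cohort
#'
#' Applies [score_tas20()], [score_aq10()] and [auto_score_aprq()] across a
#' cohort, returning one row per participant.
#'
#' @param cohort An [aprq_cohort] whose `instruments` table has columns
#'   `tas_1`..`tas_20` and `aq_1`..`aq_10` (optionally `age`).
#' @param lexicon An `emotion_lexicon` for the automated APRQ rating.
#' @param stopwords Stopword vector passed to [auto_score_aprq()].
#' @inheritParams score_tas20
#' @inheritParams score_aq10
#' @return Data frame with columns `participant_id`, `group`, `tas20_total`,
#'   `tas20_alexithymic`, `aq10_total`, `aq10_screen_positive`,
#'   `aprq_total`, and `age` when available.
#' @export
score_instruments <- function(cohort, lexicon,
                              stopwords = character(),
                              reverse_items = c(4L, 5L, 10L, 18L, 19L),
                              agree_keyed = c(1L, 7L, 8L, 10L)) {
  stopifnot(inherits(cohort, "aprq_cohort"), !is.null(cohort$instruments))
  inst <- cohort$instruments
  tas_cols <- paste0("tas_", 1:20)
  aq_cols <- paste0("aq_", 1:10)
  rows <- lapply(cohort$transcripts, function(t) {
    r <- inst[inst$participant_id == t$participant_id, , drop = FALSE]
    tas <- if (nrow(r) == 1L && all(tas_cols %in% names(r))) {
      score_tas20(as.numeric(r[1L, tas_cols]), reverse_items)
    } else list(total = NA_integer_, alexithymic = NA)
    aq <- if (nrow(r) == 1L && all(aq_cols %in% names(r))) {
      score_aq10(as.numeric(r[1L, aq_cols]), agree_keyed)
    } else list(total = NA_integer_, screen_positive = NA)
    aprq <- suppressWarnings(auto_score_aprq(t, lexicon, stopwords))
    data.frame(participant_id = t$participant_id, group = t$group,
               tas20_total = tas$total, tas20_alexithymic = tas$alexithymic,
               aq10_total = aq$total, aq10_screen_positive = aq$screen_positive,
               aprq_total = aprq$total,
               age = if (nrow(r) == 1L && "age" %in% names(r))
                 as.numeric(r$age[1L]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
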