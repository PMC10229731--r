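#' Run the full emotional-language analysis
#'
#' Orchestrates the whole pipeline on a cohort: per-participant linguistic
#' features and instrument scores; group comparisons of word counts,
#' emotion/non-emotion counts, EV, TTR and dictionary category percentages
#' (Wilcoxon rank-sum with Vargha-Delaney A); the Spearman correlation
#' matrix over EV, TTR, emotion word count, APRQ, age, TAS-20 and AQ-10
#' (plus the AQ-10/EV partial correlation controlling for TTR); the
#' provocation congruence and incongruence tables; the "feel" bigram
#' summary; and two logistic models of group membership — TAS-20 only, and
#' TAS-20 plus emotion and non-emotion word counts — compared by correct
#' classification rate and AIC, with the goodness-of-fit and influence
#' diagnostics for the linguistic model. Composite scores (EV, TTR) are
#' deliberately excluded as logistic predictors to avoid multicollinearity
#' with their component counts.
#'
#' Participants with a missing TAS-20 are dropped from the logistic models
#' only (with the dropped count logged in the report); all other analyses
#' use every participant. The report is deterministic given its inputs.
#'
#' @param cohort An [aprq_cohort] with instrument data.
#' @param lexicon An `emotion_lexicon`.
#' @param stopwords Stopword character vector.
#' @param dictionary A `category_dictionary`; defaults to one derived from
#'   the lexicon via [category_dictionary_from_lexicon()].
#' @return Object of class `aprq_report`; see Details for components.
#' @export
run_full_analysis <- function(cohort,
                              lexicon = default_emotion_lexicon(),
                              stopwords = default_stopwords(),
                              dictionary =
                                category_dictionary_from_lexicon(lexicon)) {
  stopifnot(inherits(cohort, "aprq_cohort"))
  feats <- feature_table(cohort, lexicon, stopwords, dictionary)
  scores <- score_instruments(cohort, lexicon)
  stopifnot(identical(feats$participant_id, scores$participant_id))
  tab <- cbind(feats, scores[setdiff(names(scores),
                                     c("participant_id", "group"))])
  asd <- tab$group == "ASD"

  cmp_vars <- c(raw_word_count = "Raw word count",
                content_word_count = "Content word count",
                distinct_word_count = "Distinct word count",
                emotion_token_count = "Emotion word count",
                non_emotion_word_count = "Non-emotion word count",
                ev_percent = "EV", ttr_percent = "TTR")
  cat_cols <- grep("^pct_", names(tab), value = TRUE)
  cmp_vars <- c(cmp_vars, stats::setNames(cat_cols,
                                          paste0(sub("^pct_", "", cat_cols),
                                                 " %")))
  names(cmp_vars) <- NULL
  vars <- c("raw_word_count", "content_word_count", "distinct_word_count",
            "emotion_token_count", "non_emotion_word_count", "ev_percent",
            "ttr_percent", cat_cols)
  comparisons <- lapply(seq_along(vars), function(i) {
    group_comparison(tab[[vars[i]]][asd], tab[[vars[i]]][!asd],
                     type = "wilcoxon", label = vars[i])
  })
  names(comparisons) <- vars
  comparison_table <- do.call(rbind, lapply(comparisons, function(gc) {
    data.frame(variable = gc$label,
               asd_mean = mean(tab[[gc$label]][asd], na.rm = TRUE),
               asd_sd = stats::sd(tab[[gc$label]][asd]),
               nt_mean = mean(tab[[gc$label]][!asd], na.rm = TRUE),
               nt_sd = stats::sd(tab[[gc$label]][!asd]),
               W = gc$statistic, p_value = gc$p_value,
               vda = gc$effect_size, interpretation = gc$interpretation,
               stringsAsFactors = FALSE)
  }))
  rownames(comparison_table) <- NULL

  cor_vars <- c(ev_percent = "EV", ttr_percent = "TTR",
                emotion_token_count = "Emotion word count",
                aprq_total = "APRQ", age = "Age",
                tas20_total = "TAS-20", aq10_total = "AQ-10")
  cor_vars <- cor_vars[names(cor_vars) %in% names(tab) &
                         vapply(names(cor_vars),
                                function(v) !all(is.na(tab[[v]])), TRUE)]
  k <- length(cor_vars)
  labels <- unname(cor_vars)
  rho <- matrix(1, k, k, dimnames = list(labels, labels))
  pmat <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i < j) {
    sc <- spearman_cor(tab[[names(cor_vars)[i]]], tab[[names(cor_vars)[j]]])
    rho[i, j] <- rho[j, i] <- sc$rho
    pmat[i, j] <- pmat[j, i] <- sc$p_value
  }
  partial <- if (all(c("aq10_total", "ev_percent", "ttr_percent") %in%
                       names(tab))) {
    partial_spearman(tab$aq10_total, tab$ev_percent, tab$ttr_percent)
  }

  congr <- congruence_table(cohort, dictionary, stopwords = stopwords)
  incongr <- incongruence_tests(cohort, dictionary, stopwords = stopwords)
  bigrams <- feel_bigram_summary(cohort, stopwords, lexicon)

  # logistic models on TAS-20 completers
  mdata <- tab[!is.na(tab$tas20_total),
               c("group", "tas20_total", "emotion_token_count",
                 "non_emotion_word_count")]
  mdata$asd <- as.integer(mdata$group == "ASD")
  n_dropped <- nrow(tab) - nrow(mdata)
  model_tas <- logistic_fit(asd ~ tas20_total, mdata)
  model_full <- logistic_fit(asd ~ tas20_total + emotion_token_count +
                               non_emotion_word_count, mdata)
  diag_full <- list(
    hosmer_lemeshow = hosmer_lemeshow(model_full),
    vif = vif(mdata[, c("tas20_total", "emotion_token_count",
                        "non_emotion_word_count")]),
    box_tidwell = box_tidwell(asd ~ tas20_total + emotion_token_count +
                                non_emotion_word_count, mdata,
                              shift = TRUE),
    cooks = cooks_distances(model_full))

  structure(list(
    features = tab,
    comparisons = comparisons,
    comparison_table = comparison_table,
    correlations = list(rho = rho, p = pmat,
                        partial_aq10_ev_given_ttr = partial),
    congruence = congr,
    incongruence = incongr,
    bigrams = bigrams,
    models = list(tas20_only = model_tas, tas20_linguistic = model_full,
                  diagnostics = diag_full,
                  n_dropped_missing_tas = n_dropped),
    log = list(n_participants = nrow(tab),
               n_asd = sum(asd), n_nt = sum(!asd),
               lexicon_terms = length(lexicon$terms),
               stopword_count = length(stopwords),
               n_dropped_missing_tas = n_dropped,
               cohort_checksum = cohort_checksum(cohort))),
    class = "aprq_report")
}

# md5 of the serialized transcripts+instruments, for report traceability
cohort_checksum <- function(cohort) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(cohort$transcripts, cohort$instruments), tf, version = 2L,
          compress = FALSE)
  unname(tools::md5sum(tf))
}

#' @export
print.aprq_report <- function(x, digits = 3, ...) {
  cat("APRQ emotional-language analysis:", x$log$n_participants,
      "participants (", x$log$n_asd, "ASD /", x$log$n_nt, "NT )\n")
  cat("Lexicon terms:", x$log$lexicon_terms,
      "| stopwords:", x$log$stopword_count, "\n\n")
  cat("Group comparisons (Wilcoxon rank-sum, Vargha-Delaney A):\n")
  ct <- x$comparison_table
  ct[2:8] <- lapply(ct[2:8], round, digits)
  print(ct, row.names = FALSE)
  cat("\nCongruent emotion words by provocation (Welch t, ASD - NT):\n")
  cg <- x$congruence
  cg[, vapply(cg, is.numeric, TRUE)] <-
    round(cg[, vapply(cg, is.numeric, TRUE)], digits)
  print(cg, row.names = FALSE)
  cat("\n'feel' bigrams: ", x$bigrams$counts[["all"]], " total, ",
      x$bigrams$counts[["content"]], " after stopword filtering, ",
      x$bigrams$counts[["residual"]], " residual non-lexicon\n\n", sep = "")
  cat("Model 1 (TAS-20 only):\n")
  print(x$models$tas20_only)
  cat("\nModel 2 (TAS-20 + emotion + non-emotion word counts):\n")
  print(x$models$tas20_linguistic)
  hl <- x$models$diagnostics$hosmer_lemeshow
  cat(sprintf("\nHosmer-Lemeshow: chi2(%d) = %.2f, p = %.2f | max VIF = %.2f | max Cook's d = %.3f\n",
              hl$df, hl$chi2, hl$p_value,
              max(x$models$diagnostics$vif),
              max(x$models$diagnostics$cooks$distances)))
  invisible(x)
}

#' Density plot of a feature by group
#'
#' Optional convenience plot mirroring the usual presentation of skewed
#' linguistic counts: overlaid kernel densities for the two groups.
#'
#' @param x An `aprq_report`.
#' @param variable Feature column to plot (default raw word count).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.aprq_report <- function(x, variable = "raw_word_count", ...) {
  tab <- x$features
  asd <- stats::density(tab[[variable]][tab$group == "ASD"], from = 0)
  nt <- stats::density(tab[[variable]][tab$group == "NT"], from = 0)
  graphics::plot(asd, col = "firebrick", lwd = 2, main = variable,
                 xlab = variable,
                 ylim = c(0, max(asd$y, nt$y)), ...)
  graphics::lines(nt, col = "steelblue", lwd = 2)
  graphics::legend("topright", legend = c("ASD", "NT"), lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n")
  invisible(x)
}

#' Write report tables to disk
#'
#' Emits `features.csv`, `group_comparisons.csv`, `congruence.csv`,
#' `incongruence.csv`, `correlations.csv`, `bigrams.csv` and `report.json`
#' (models, diagnostics and run log) into a directory.
#'
#' @param report An `aprq_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "aprq_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparison_table,
                   file.path(dir, "group_comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$congruence, file.path(dir, "congruence.csv"),
                   row.names = FALSE)
  utils::write.csv(report$incongruence, file.path(dir, "incongruence.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$correlations$rho),
                   file.path(dir, "correlations.csv"))
  utils::write.csv(report$bigrams$all, file.path(dir, "bigrams.csv"),
                   row.names = FALSE)
  fit_json <- function(m) {
    list(coefficients = m$coefficients, r2_cox_snell = m$r2_cox_snell,
         r2_nagelkerke = m$r2_nagelkerke, aic = m$aic,
         model_chi2 = m$model_chi2, model_df = m$model_df,
         model_p = m$model_p, classification_rate = m$classification_rate,
         baseline_rate = m$baseline_rate, n = m$n)
  }
  diag <- report$models$diagnostics
  jsonlite::write_json(list(
    log = report$log,
    models = list(tas20_only = fit_json(report$models$tas20_only),
                  tas20_linguistic = fit_json(report$models$tas20_linguistic)),
    diagnostics = list(
      hosmer_lemeshow = diag$hosmer_lemeshow[c("chi2", "df", "p_value")],
      vif = as.list(diag$vif),
      box_tidwell = diag$box_tidwell,
      max_cooks_distance = max(diag$cooks$distances),
      cooks_flagged = diag$cooks$flagged),
    partial_correlation_aq10_ev_given_ttr =
      report$correlations$partial_aq10_ev_given_ttr),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
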