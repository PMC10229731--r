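#' Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison. The p-value is
#' exact (by enumeration of the rank-sum distribution) when both samples
#' have 10 or fewer observations and there are no ties across the pooled
#' data, and otherwise uses the normal approximation with tie and continuity
#' corrections. Exact mode can be forced for larger tie-free samples with
#' `exact = TRUE` (the shift-algorithm enumeration used by R scales well
#' beyond n = 10 but is documented as an opt-in because it is slower).
#' When every value in both samples is identical the test is vacuous and
#' p = 1 is returned by convention.
#'
#' @param x,y Nonempty numeric samples.
#' @param exact `NULL` (auto rule above), or logical to force.
#' @return List with `statistic` (the rank-sum `W` as reported by
#'   [stats::wilcox.test()]), `p_value`, and `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = unname(length(x) * length(y) / 2), p_value = 1,
                method = "degenerate (all values identical)"))
  }
  ties <- anyDuplicated(pooled) > 0L
  if (is.null(exact)) exact <- length(x) <= 10L && length(y) <= 10L && !ties
  if (exact && ties) {
    warning("ties present; falling back to normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal approximation")
}

#' Vargha-Delaney A effect size
#'
#' Probability-of-superiority effect size for two samples:
#' `A = (#\{x > y\} + 0.5 #\{x = y\}) / (n_x n_y)` over all pairs, computed
#' via the rank-sum identity. A value of 1 means complete stochastic
#' dominance of the first sample over the second, 0 the opposite, and 0.5 no
#' difference. The interpretation bands are: negligible 0.45-0.55; small
#' 0.56-0.63 or 0.35-0.44; medium 0.64-0.70 or 0.30-0.34; large above 0.70
#' or below 0.30 (boundaries between printed bands are assigned to the
#' milder interpretation, giving a partition of \[0, 1\]).
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `A` and `interpretation` (one of `negligible`, `small`,
#'   `medium`, `large`).
#' @export
vda_effect_size <- function(x, y) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  A <- (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
  list(A = A, interpretation = vda_interpretation(A))
}

#' @rdname vda_effect_size
#' @param A A Vargha-Delaney A value in \[0, 1\].
#' @export
vda_interpretation <- function(A) {
  stopifnot(A >= 0, A <= 1)
  if (A >= 0.45 && A < 0.56) "negligible"
  else if ((A >= 0.35 && A < 0.45) || (A >= 0.56 && A < 0.64)) "small"
  else if ((A >= 0.30 && A < 0.35) || (A >= 0.64 && A <= 0.70)) "medium"
  else "large"
}

#' Spearman rank correlation
#'
#' Spearman's rho on average ranks (ties allowed), with a two-sided p-value
#' from the t approximation on `df = n - 2`.
#'
#' @param x,y Aligned numeric vectors, `n >= 3`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined", call. = FALSE)
    return(list(rho = NA_real_, p_value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

#' Partial Spearman correlation
#'
#' First-order partial rank correlation of `x` and `y` controlling for `z`,
#' via the standard partial-correlation formula applied to the pairwise
#' Spearman correlations:
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#'
#' @param x,y,z Aligned numeric vectors, `n >= 4`.
#' @return List with `rho`, `p_value` (t approximation, `df = n - 3`), `n`.
#' @export
partial_spearman <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  stopifnot(n >= 4L)
  rxy <- stats::cor(rank(x), rank(y))
  rxz <- stats::cor(rank(x), rank(z))
  ryz <- stats::cor(rank(y), rank(z))
  rho <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  tstat <- rho * sqrt((n - 3) / (1 - rho^2))
  list(rho = rho, p_value = 2 * stats::pt(-abs(tstat), df = n - 3), n = n)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom (the
#' fractional dfs typical of response-level linguistic contrasts). When
#' both groups have zero variance and equal means, `t = 0, p = 1` is
#' returned by convention.
#'
#' @param x,y Numeric samples, `n >= 2` each.
#' @return List with `t`, `df`, `p_value`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Cohen's d (pooled SD)
#'
#' `d = (mean(x) - mean(y)) / s_p` with the pooled standard deviation
#' `s_p = sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#'
#' @param x,y Numeric samples, `n >= 2` each.
#' @return Numeric scalar (0 when the pooled SD is 0 and means are equal).
#' @export
cohen_d <- function(x, y) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
               (nx + ny - 2))
  if (sp == 0) {
    if (mean(x) == mean(y)) return(0)
    stop("zero pooled SD with unequal means", call. = FALSE)
  }
  (mean(x) - mean(y)) / sp
}

#' Pearson chi-square test of independence
#'
#' Pearson chi-square on an r x c count table, `df = (r-1)(c-1)`, without
#' continuity correction.
#'
#' @param counts Matrix of nonnegative counts, at least 2 x 2.
#' @return List with `chi2`, `df`, `p_value`.
#' @export
chi_square_independence <- function(counts) {
  m <- as.matrix(counts)
  stopifnot(nrow(m) >= 2L, ncol(m) >= 2L, all(m >= 0))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal total; chi-square undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' Nonparametric group comparison with effect size
#'
#' Convenience wrapper pairing a test with its effect size the way the
#' report tables need them: `"wilcoxon"` pairs the rank-sum test with
#' Vargha-Delaney A, `"welch"` pairs the Welch t-test with Cohen's d
#' (interpreted on the usual 0.2/0.5/0.8 bands). Effects are oriented
#' x minus y.
#'
#' @param x,y Numeric samples.
#' @param type `"wilcoxon"` or `"welch"`.
#' @param label Optional label carried into the result.
#' @return Object of class `group_comparison`: list with `label`,
#'   `statistic_name`, `statistic`, `df` (or `NA`), `p_value`,
#'   `effect_size_name`, `effect_size`, `interpretation`, `n_x`, `n_y`.
#' @export
group_comparison <- function(x, y, type = c("wilcoxon", "welch"),
                             label = NULL) {
  type <- match.arg(type)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (type == "wilcoxon") {
    ts <- wilcoxon_rank_sum(x, y)
    es <- vda_effect_size(x, y)
    out <- list(label = label, statistic_name = "W",
                statistic = ts$statistic, df = NA_real_,
                p_value = ts$p_value, effect_size_name = "VD.A",
                effect_size = es$A, interpretation = es$interpretation,
                n_x = length(x), n_y = length(y))
  } else {
    ts <- welch_t(x, y)
    d <- cohen_d(x, y)
    interp <- if (abs(d) < 0.2) "negligible" else if (abs(d) < 0.5) "small"
              else if (abs(d) < 0.8) "medium" else "large"
    out <- list(label = label, statistic_name = "t", statistic = ts$t,
                df = ts$df, p_value = ts$p_value, effect_size_name = "d",
                effect_size = d, interpretation = interp,
                n_x = length(x), n_y = length(y))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s%s = %.3f%s, p = %.4f, %s = %.3f (%s), n = %d vs %d\n",
              if (is.null(x$label)) "" else paste0(x$label, ": "),
              x$statistic_name, x$statistic,
              if (is.na(x$df)) "" else sprintf(", df = %.2f", x$df),
              x$p_value, x$effect_size_name, x$effect_size,
              x$interpretation, x$n_x, x$n_y))
  invisible(x)
}
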