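#' Logistic regression with reporting and diagnostics
#'
#' Fits a binomial logistic regression by iteratively reweighted least
#' squares (convergence tolerance 1e-8) and assembles the quantities a
#' group-classification report needs: coefficient table with Wald z, odds
#' ratios with 95% Wald confidence intervals, Cox & Snell and Nagelkerke
#' pseudo-R-squared, AIC, the model likelihood-ratio chi-square, and correct
#' classification rate at the 0.5 probability threshold alongside the
#' majority-class baseline rate.
#'
#' Cox & Snell R2 = `1 - exp((D - D0)/n)` where `D`/`D0` are the model and
#' null deviances; Nagelkerke rescales it by its maximum
#' `1 - exp(-D0/n)`, so Nagelkerke >= Cox & Snell always. Perfect separation
#' (fitted probabilities numerically 0/1 on every observation) aborts the
#' fit with a diagnostic error rather than returning meaningless
#' coefficients.
#'
#' @param formula Model formula; the response must be binary (0/1, logical,
#'   or a two-level factor whose second level is the event).
#' @param data Data frame with no missing cells in the model variables.
#' @return Object of class `logistic_fit`: list with `fit` (the underlying
#'   `glm`), `coefficients` (data frame: `estimate`, `se`, `z`, `p`,
#'   `odds_ratio`, `or_low`, `or_high`), `r2_cox_snell`, `r2_nagelkerke`,
#'   `aic`, `model_chi2`, `model_df`, `model_p`, `classification_rate` and
#'   `baseline_rate` (percent), `n`, and `outcome` (the 0/1 vector used).
#' @export
logistic_fit <- function(formula, data) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1)) || length(unique(y)) != 2L) {
    stop("outcome must be binary with both classes present", call. = FALSE)
  }
  fit <- stats::glm(formula, data = data, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8,
                                                 maxit = 100L))
  p_hat <- stats::fitted(fit)
  if (all(abs(p_hat - y) < 1e-6)) {
    stop("perfect separation detected: fitted probabilities are numerically ",
         "0/1 for every observation; coefficients are not identifiable",
         call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                      se = sm[, 2L], z = sm[, 3L], p = sm[, 4L],
                      odds_ratio = exp(sm[, 1L]),
                      or_low = exp(sm[, 1L] - 1.96 * sm[, 2L]),
                      or_high = exp(sm[, 1L] + 1.96 * sm[, 2L]),
                      row.names = NULL, stringsAsFactors = FALSE)
  n <- length(y)
  D <- fit$deviance; D0 <- fit$null.deviance
  r2_cs <- 1 - exp((D - D0) / n)
  r2_max <- 1 - exp(-D0 / n)
  class_rate <- 100 * mean((p_hat >= 0.5) == (y == 1))
  base_rate <- 100 * max(mean(y), 1 - mean(y))
  structure(list(
    fit = fit, coefficients = coefs,
    r2_cox_snell = r2_cs, r2_nagelkerke = r2_cs / r2_max,
    aic = stats::AIC(fit),
    model_chi2 = D0 - D, model_df = fit$df.null - fit$df.residual,
    model_p = stats::pchisq(D0 - D, df = fit$df.null - fit$df.residual,
                            lower.tail = FALSE),
    classification_rate = class_rate, baseline_rate = base_rate,
    n = n, outcome = y), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic regression (n =", x$n, ")\n")
  tab <- x$coefficients
  tab[-1L] <- lapply(tab[-1L], round, 4L)
  print(tab, row.names = FALSE)
  cat(sprintf("Model chi2(%d) = %.2f, p = %.4g | AIC = %.2f\n",
              x$model_df, x$model_chi2, x$model_p, x$aic))
  cat(sprintf("R2: Cox & Snell = %.2f, Nagelkerke = %.2f\n",
              x$r2_cox_snell, x$r2_nagelkerke))
  cat(sprintf("Correct classification: %.2f%% (baseline %.2f%%)\n",
              x$classification_rate, x$baseline_rate))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
predict.logistic_fit <- function(object, newdata = NULL,
                                 type = "response", ...) {
  stats::predict(object$fit, newdata = newdata, type = type, ...)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  stats::residuals(object$fit, ...)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Groups observations into (by default) deciles of fitted risk — equal
#' frequency groups with tied fitted probabilities kept together — and
#' compares observed with expected event counts:
#' `chi2 = sum over groups of (o1-e1)^2/e1 + (o0-e0)^2/e0`, with
#' `df = g - 2`. Groups whose expected count is 0 are merged into their
#' neighbour with a warning.
#'
#' @param fit A `logistic_fit`.
#' @param n_groups Number of risk groups (default 10, hence df 8).
#' @return List with `chi2`, `df`, `p_value`, `n_groups_used`, and the
#'   per-group `table` (observed/expected).
#' @export
hosmer_lemeshow <- function(fit, n_groups = 10L) {
  stopifnot(inherits(fit, "logistic_fit"), fit$n >= n_groups)
  p <- stats::fitted(fit$fit)
  y <- fit$outcome
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = n_groups + 1L),
                               type = 7L))
  g <- cut(p, breaks = br, include.lowest = TRUE)
  grp <- split(seq_along(p), g, drop = TRUE)
  obs1 <- vapply(grp, function(i) sum(y[i]), 0)
  exp1 <- vapply(grp, function(i) sum(p[i]), 0)
  nn <- lengths(grp)
  # merge groups with degenerate expected counts into the previous group
  while (length(nn) > 2L &&
         any(pmin(exp1, nn - exp1) <= .Machine$double.eps^0.5)) {
    j <- which(pmin(exp1, nn - exp1) <= .Machine$double.eps^0.5)[1L]
    k <- if (j == 1L) 2L else j - 1L
    obs1[k] <- obs1[k] + obs1[j]; exp1[k] <- exp1[k] + exp1[j]
    nn[k] <- nn[k] + nn[j]
    obs1 <- obs1[-j]; exp1 <- exp1[-j]; nn <- nn[-j]
    warning("merged a risk group with zero expected count", call. = FALSE)
  }
  g_used <- length(nn)
  chi2 <- sum((obs1 - exp1)^2 / exp1 +
                ((nn - obs1) - (nn - exp1))^2 / (nn - exp1))
  df <- g_used - 2L
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       n_groups_used = g_used,
       table = data.frame(n = nn, observed = obs1, expected = exp1))
}

#' Box-Tidwell linearity-of-the-logit check
#'
#' Augments the logistic model with an `x * log(x)` interaction term for
#' each continuous predictor and reports the Wald p-value of each
#' interaction; a significant term flags departure from linearity in the
#' logit. Continuous predictors must be strictly positive; when zeros are
#' present set `shift = TRUE` to add 1 to the offending predictors before
#' forming the log terms (the shift is applied to the interaction terms
#' only, and is reported in the output).
#'
#' @param formula Base model formula.
#' @param data Data frame.
#' @param continuous Character vector of continuous predictor names to
#'   check; default: all numeric predictors with more than two distinct
#'   values.
#' @param shift Add 1 to zero-containing predictors (default `FALSE`:
#'   zeros are an error).
#' @return Data frame with columns `term`, `p_value`, `shifted`.
#' @export
box_tidwell <- function(formula, data, continuous = NULL, shift = FALSE) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  preds <- attr(stats::terms(mf), "term.labels")
  if (is.null(continuous)) {
    continuous <- preds[vapply(preds, function(v) {
      is.numeric(data[[v]]) && length(unique(data[[v]])) > 2L
    }, TRUE)]
  }
  if (!length(continuous)) stop("no continuous predictors", call. = FALSE)
  aug <- data
  shifted <- logical(length(continuous))
  bt_terms <- character(length(continuous))
  for (i in seq_along(continuous)) {
    v <- continuous[i]
    x <- aug[[v]]
    if (any(x < 0)) stop("predictor '", v, "' has negative values",
                         call. = FALSE)
    if (any(x == 0)) {
      if (!shift) {
        stop("predictor '", v, "' contains zeros; rerun with shift = TRUE",
             call. = FALSE)
      }
      x <- x + 1
      shifted[i] <- TRUE
    }
    nm <- paste0(".bt_", v)
    aug[[nm]] <- x * log(x)
    bt_terms[i] <- nm
  }
  f_aug <- stats::update(stats::as.formula(formula),
                         stats::as.formula(paste("~ . +",
                                                 paste(bt_terms,
                                                       collapse = " + "))))
  fit <- logistic_fit(f_aug, aug)
  ct <- fit$coefficients
  data.frame(term = continuous,
             p_value = ct$p[match(bt_terms, ct$term)],
             shifted = shifted, stringsAsFactors = FALSE)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the ordinary
#' least-squares regression of predictor j on the remaining predictors.
#' Perfectly collinear predictors yield `Inf`.
#'
#' @param design Data frame or matrix of numeric predictors (>= 2 columns),
#'   or a `logistic_fit` (its predictor columns are used).
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design) {
  if (inherits(design, "logistic_fit")) {
    design <- stats::model.matrix(design$fit)[, -1L, drop = FALSE]
  }
  m <- as.matrix(as.data.frame(design))
  stopifnot(ncol(m) >= 2L)
  out <- vapply(seq_len(ncol(m)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(m[, j] ~ m[, -j, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  stats::setNames(out, colnames(m))
}

#' Cook's distances for a logistic fit
#'
#' Standard one-step influence approximation on the working response (as
#' given by [stats::cooks.distance()] for a `glm`); observations above the
#' conventional 0.5 threshold are flagged.
#'
#' @param fit A `logistic_fit`.
#' @param threshold Flagging threshold (default 0.5).
#' @return List with `distances` (numeric) and `flagged` (indices above the
#'   threshold).
#' @export
cooks_distances <- function(fit, threshold = 0.5) {
  stopifnot(inherits(fit, "logistic_fit"))
  d <- stats::cooks.distance(fit$fit)
  list(distances = unname(d), flagged = which(d > threshold))
}
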