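# independent enumeration oracle for the exact rank-sum p-value
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * length(y) / 2
  combos <- utils::combn(length(pooled), nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

test_that("Wilcoxon exact p equals full enumeration for small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4))$p_value, 1 / 3)
  set.seed(13)
  for (i in 1:8) {
    nx <- sample(3:8, 1); ny <- sample(3:8, 1)
    repeat {
      x <- round(rnorm(nx), 3); y <- round(rnorm(ny, 0.5), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    w <- wilcoxon_rank_sum(x, y)
    expect_identical(w$method, "exact")
    expect_equal(w$p_value, enum_ranksum_p(x, y))
  }
})

test_that("Wilcoxon approximation is close to enumeration at n = 8-10", {
  set.seed(14)
  for (i in 1:5) {
    n <- sample(8:10, 1)
    repeat {
      x <- round(rnorm(n), 3); y <- round(rnorm(n, 0.3), 3)
      if (!anyDuplicated(c(x, y))) break
    }
    p_exact <- wilcoxon_rank_sum(x, y, exact = TRUE)$p_value
    p_approx <- wilcoxon_rank_sum(x, y, exact = FALSE)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("Wilcoxon degenerate and dominance cases", {
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5))$p_value, 1)
  w <- wilcoxon_rank_sum(1:5, 1:5 + 1000)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 2 / choose(10, 5))
})

test_that("Vargha-Delaney A: closed cases and brute-force equality", {
  expect_equal(vda_effect_size(c(1, 2, 3), c(1, 2, 3))$A, 0.5)
  expect_identical(vda_effect_size(c(1, 2, 3), c(1, 2, 3))$interpretation,
                   "negligible")
  expect_equal(vda_effect_size(c(10, 11), c(1, 2))$A, 1)
  expect_identical(vda_effect_size(c(10, 11), c(1, 2))$interpretation,
                   "large")
  expect_equal(vda_effect_size(c(1, 3), c(2, 4))$A, 0.25)
  expect_identical(vda_effect_size(c(1, 3), c(2, 4))$interpretation, "large")

  brute_A <- function(x, y) {
    s <- 0
    for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
    s / (length(x) * length(y))
  }
  set.seed(15)
  for (i in 1:20) {
    x <- sample(0:8, sample(2:50, 1), replace = TRUE)
    y <- sample(0:8, sample(2:50, 1), replace = TRUE)
    expect_equal(vda_effect_size(x, y)$A, brute_A(x, y))
  }
})

test_that("A(x,y) + A(y,x) = 1 and the bands partition [0,1]", {
  set.seed(16)
  for (i in 1:15) {
    repeat {
      x <- rnorm(sample(2:20, 1)); y <- rnorm(sample(2:20, 1))
      if (!anyDuplicated(c(x, y))) break
    }
    expect_equal(vda_effect_size(x, y)$A + vda_effect_size(y, x)$A, 1)
  }
  grid <- seq(0, 1, by = 0.001)
  bands <- vapply(grid, vda_interpretation, "")
  expect_true(all(bands %in% c("negligible", "small", "medium", "large")))
  # symmetric interpretation around 0.5 at the printed boundaries
  expect_identical(vda_interpretation(0.5), "negligible")
  expect_identical(vda_interpretation(0.36), "small")
  expect_identical(vda_interpretation(0.60), "small")
  expect_identical(vda_interpretation(0.32), "medium")
  expect_identical(vda_interpretation(0.67), "medium")
  expect_identical(vda_interpretation(0.72), "large")
  expect_identical(vda_interpretation(0.25), "large")
})

test_that("Spearman rho on ranks, with ties, matches the direct formula", {
  expect_equal(spearman_cor(1:8, (1:8)^2)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)
  x <- c(1, 2, 2, 4, 5, 6)
  y <- c(3, 1, 4, 4, 6, 9)
  rx <- rank(x); ry <- rank(y)
  expected <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  got <- spearman_cor(x, y)
  expect_equal(got$rho, expected)
  tt <- expected * sqrt(4 / (1 - expected^2))
  expect_equal(got$p_value, 2 * pt(-abs(tt), 4))
  expect_warning(spearman_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("partial Spearman equals correlation of rank residuals", {
  set.seed(17)
  for (i in 1:5) {
    z <- rnorm(30)
    x <- z + rnorm(30)
    y <- -z + rnorm(30)
    res_x <- resid(lm(rank(x) ~ rank(z)))
    res_y <- resid(lm(rank(y) ~ rank(z)))
    expect_equal(partial_spearman(x, y, z)$rho, cor(res_x, res_y))
  }
})

test_that("Welch t and Cohen's d: closed form and antisymmetry", {
  x <- c(1, 2, 3, 4); y <- c(3, 5, 7, 9, 11)
  got <- welch_t(x, y)
  se <- sqrt(var(x) / 4 + var(y) / 5)
  expect_equal(got$t, (mean(x) - mean(y)) / se)
  df_expect <- se^4 / ((var(x) / 4)^2 / 3 + (var(y) / 5)^2 / 4)
  expect_equal(got$df, df_expect)
  sp <- sqrt((3 * var(x) + 4 * var(y)) / 7)
  expect_equal(cohen_d(x, y), (mean(x) - mean(y)) / sp)
  expect_equal(welch_t(y, x)$t, -got$t)
  expect_equal(cohen_d(y, x), -cohen_d(x, y))
  expect_equal(welch_t(c(1, 1), c(1, 1))$t, 0)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(cohen_d(x, x), 0)
})

test_that("chi-square of independence: hand formula and df", {
  tab <- matrix(c(10, 20, 20, 10), 2)
  got <- chi_square_independence(tab)
  expect_equal(got$chi2, 20 / 3)
  expect_identical(got$df, 1L)
  prop <- outer(c(2, 3), c(10, 20, 30))
  expect_equal(chi_square_independence(prop)$chi2, 0)
  expect_identical(chi_square_independence(matrix(1, 2, 5))$df, 4L)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2,
                                              byrow = TRUE)),
               "marginal")
})

test_that("logistic fit: null model, cross-product OR, pseudo-R2 ordering", {
  d <- data.frame(y = rep(c(0, 1), 25))
  f0 <- logistic_fit(y ~ 1, d)
  expect_equal(unname(coef(f0)), 0, tolerance = 1e-6)
  expect_equal(f0$classification_rate, f0$baseline_rate)

  # single binary predictor: OR equals the 2x2 cross-product ratio
  counts <- c(n00 = 20, n01 = 12, n10 = 9, n11 = 24)
  d2 <- data.frame(
    x = rep(c(0, 0, 1, 1), counts),
    y = rep(c(0, 1, 0, 1), counts))
  f2 <- logistic_fit(y ~ x, d2)
  or_hand <- (counts["n11"] * counts["n00"]) /
    (counts["n10"] * counts["n01"])
  expect_equal(unname(f2$coefficients$odds_ratio[2]), unname(or_hand))

  set.seed(18)
  for (i in 1:6) {
    n <- 120
    dd <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    eta <- -0.3 + 0.8 * dd$x1 - 0.5 * dd$x2
    dd$y <- rbinom(n, 1, plogis(eta))
    ff <- logistic_fit(y ~ x1 + x2, dd)
    expect_gte(ff$r2_nagelkerke, ff$r2_cox_snell)
    expect_gte(ff$r2_cox_snell, 0)
    expect_lte(ff$r2_nagelkerke, 1)
    expect_equal(ff$aic, ff$fit$deviance + 2 * 3)
  }
})

test_that("logistic coefficients are recovered from simulated data", {
  beta <- c(`(Intercept)` = -0.5, x1 = 0.8, x2 = -0.6)
  for (n in c(200, 2000)) {
    set.seed(19)
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- rbinom(n, 1, plogis(beta[1] + beta[2] * d$x1 + beta[3] * d$x2))
    f <- logistic_fit(y ~ x1 + x2, d)
    expect_true(all(abs(f$coefficients$estimate - beta) <=
                      2 * f$coefficients$se))
  }
})

test_that("perfect separation aborts with a diagnostic", {
  d <- data.frame(x = c(1, 2, 3, 10, 11, 12), y = c(0, 0, 0, 1, 1, 1))
  expect_error(suppressWarnings(logistic_fit(y ~ x, d)), "separation")
})

test_that("Hosmer-Lemeshow: df rule and a hand-computed fixture", {
  set.seed(20)
  n <- 200
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.4 * d$x))
  f <- logistic_fit(y ~ x, d)
  hl <- hosmer_lemeshow(f, n_groups = 10)
  expect_identical(hl$df, 8L)

  # g = 4 on 40 points: recompute chi2 from the quartile groups directly
  set.seed(21)
  d2 <- data.frame(x = rnorm(40))
  d2$y <- rbinom(40, 1, plogis(d2$x))
  f2 <- logistic_fit(y ~ x, d2)
  hl4 <- hosmer_lemeshow(f2, n_groups = 4)
  p <- fitted(f2$fit)
  br <- unique(quantile(p, probs = seq(0, 1, 0.25)))
  g <- cut(p, br, include.lowest = TRUE)
  chi2_hand <- sum(vapply(split(seq_len(40), g), function(i) {
    o1 <- sum(d2$y[i]); e1 <- sum(p[i]); nn <- length(i)
    (o1 - e1)^2 / e1 + ((nn - o1) - (nn - e1))^2 / (nn - e1)
  }, 0))
  expect_equal(hl4$chi2, chi2_hand)
  expect_identical(hl4$df, 2L)
})

test_that("Hosmer-Lemeshow p is roughly uniform under a calibrated model", {
  set.seed(22)
  ps <- replicate(60, {
    n <- 150
    d <- data.frame(x = rnorm(n))
    d$y <- rbinom(n, 1, plogis(-0.2 + 0.7 * d$x))
    hosmer_lemeshow(logistic_fit(y ~ x, d), n_groups = 10)$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
  expect_gt(mean(ps < 0.05), -0.001)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("Box-Tidwell flags curvature and enforces positivity", {
  set.seed(23)
  n <- 400
  d <- data.frame(x = rexp(n) + 0.5)
  d$y <- rbinom(n, 1, plogis(-0.5 + 0.8 * d$x))
  bt <- box_tidwell(y ~ x, d)
  expect_gt(bt$p_value, 0.01)

  d$y2 <- rbinom(n, 1, plogis(-2 + 4 * (log(d$x))^2))
  bt2 <- suppressWarnings(box_tidwell(y2 ~ x, d))
  expect_lt(bt2$p_value, 0.05)

  d$xz <- d$x; d$xz[1] <- 0
  expect_error(box_tidwell(y ~ xz, d), "zeros")
  expect_silent(box_tidwell(y ~ xz, d, shift = TRUE))
})

test_that("VIF: orthogonality, collinearity, and agreement with car", {
  set.seed(24)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n); x3 <- 0.9 * x1 + rnorm(n, sd = 0.3)
  v <- vif(data.frame(x1, x2, x3))
  expect_lt(v[["x2"]], 1.5)    # orthogonal to the collinear pair
  expect_gt(v[["x1"]], 2)      # x3 is built from x1, inflating both
  expect_gt(v[["x3"]], 2)
  dup <- vif(data.frame(a = x1, b = x1, c = x2))
  expect_true(is.infinite(dup[["a"]]))
  if (requireNamespace("car", quietly = TRUE)) {
    d <- data.frame(y = rbinom(n, 1, 0.5), x1, x2, x3)
    f <- suppressWarnings(glm(y ~ x1 + x2 + x3, binomial, d))
    expect_equal(unname(vif(d[, c("x1", "x2", "x3")])),
                 unname(car::vif(lm(rnorm(n) ~ x1 + x2 + x3, d))),
                 tolerance = 1e-8)
  }
})

test_that("Cook's distances match the influence closed form", {
  set.seed(25)
  n <- 60
  d <- data.frame(x = rnorm(n))
  d$y <- rbinom(n, 1, plogis(0.8 * d$x))
  f <- logistic_fit(y ~ x, d)
  cd <- cooks_distances(f)
  # independent computation from the IRLS weights and hat matrix
  X <- model.matrix(f$fit)
  p <- fitted(f$fit)
  w <- p * (1 - p)
  Wh <- sqrt(w)
  H <- (Wh * X) %*% solve(crossprod(X * sqrt(w))) %*% t(X * Wh)
  h <- diag(H)
  r_std <- (d$y - p) / sqrt(w * (1 - h))
  D <- r_std^2 * h / (ncol(X) * (1 - h))
  expect_equal(cd$distances, unname(D), tolerance = 1e-4)
  expect_length(cd$flagged, 0)
})
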