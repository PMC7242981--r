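make_exact_cor <- function(n, C, seed = 1) {
  # data whose sample correlation matrix equals C exactly: whiten a
  # random matrix, then colour it with the Cholesky factor of C
  withr::with_seed(seed, {
    p <- ncol(C)
    z <- matrix(stats::rnorm(n * p), n, p)
    z <- scale(z, center = TRUE, scale = FALSE)
    z <- z %*% solve(chol(stats::cov(z)))
    z %*% chol(C)
  })
}

test_that("composites reproduce closed-form eigenstructure", {
  # rank-1: three identical columns
  x <- withr::with_seed(1, stats::rnorm(30))
  m <- cbind(a = x, b = x, c = x)
  p <- pca_composite(m)
  expect_equal(p$eigenvalues, c(3, 0, 0), tolerance = 1e-10)
  expect_equal(p$variance_explained[1], 1)
  # equicorrelation: first eigenvalue 1 + 2r
  r <- 0.715
  C <- matrix(r, 3, 3); diag(C) <- 1
  p2 <- pca_composite(make_exact_cor(40, C))
  expect_equal(p2$eigenvalues[1], 1 + 2 * r, tolerance = 1e-8)
  expect_equal(unname(p2$loadings[, 1]), rep(1 / sqrt(3), 3),
               tolerance = 1e-6)
  expect_equal(p2$retained, 1L)
})

test_that("composite decomposition reconstructs and decorrelates", {
  x <- withr::with_seed(2, matrix(stats::rnorm(32 * 6), 32, 6))
  x[, 2] <- x[, 1] + stats::rnorm(32, sd = 0.4)
  p <- pca_composite(x)
  recon <- p$loadings %*% diag(p$eigenvalues) %*% t(p$loadings)
  expect_equal(max(abs(recon - stats::cor(x))), 0, tolerance = 1e-8)
  sc_cor <- stats::cor(p$scores)
  expect_equal(max(abs(sc_cor[upper.tri(sc_cor)])), 0, tolerance = 1e-8)
  expect_equal(sum(p$eigenvalues), 6, tolerance = 1e-10)
  # sign convention: positive mean loadings everywhere
  expect_true(all(colMeans(p$loadings) >= -1e-12))
})

test_that("the dominant eigenvalue matches a power-iteration oracle", {
  power_iterate <- function(S, iters = 2000) {
    v <- rep(1, ncol(S)) / sqrt(ncol(S))
    for (i in seq_len(iters)) {
      v <- S %*% v
      v <- v / sqrt(sum(v^2))
    }
    as.numeric(t(v) %*% S %*% v)
  }
  withr::with_seed(3, {
    for (i in 1:5) {
      x <- matrix(stats::rnorm(40 * 6), 40, 6)
      p <- pca_composite(x)
      expect_equal(p$eigenvalues[1], power_iterate(stats::cor(x)),
                   tolerance = 1e-6)
    }
  })
})

test_that("a cross-check against prcomp agrees on loadings", {
  x <- withr::with_seed(4, matrix(stats::rnorm(32 * 3), 32, 3))
  x[, 2] <- x[, 1] + stats::rnorm(32, sd = 0.6)
  p <- pca_composite(x)
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  for (j in 1:3) {
    expect_equal(abs(p$loadings[, j]), abs(unname(pr$rotation[, j])),
                 tolerance = 1e-8)
    expect_equal(p$eigenvalues[j], unname(pr$sdev[j]^2), tolerance = 1e-8)
  }
})

test_that("degenerate composite inputs are refused with clear messages", {
  x <- matrix(stats::rnorm(30), 10, 3)
  x[, 2] <- 5
  colnames(x) <- c("a", "const", "c")
  expect_error(pca_composite(x), "const")
  expect_error(pca_composite(matrix(1:6, 2, 3)), "participants")
})

test_that("correlation cells match known coefficients and p values", {
  x <- 1:32
  expect_equal(correlate(x, x)$coefficient, 1)
  expect_lt(correlate(x, x)$p_value, 1e-12)
  expect_equal(correlate(x, -x, method = "spearman")$coefficient, -1)
  # rho = 0.35 at n = 32 sits right at the two-sided 5% boundary
  y <- make_exact_cor(32, matrix(c(1, 0.35, 0.35, 1), 2), seed = 5)
  cell <- correlate(rank(y[, 1]), rank(y[, 2]), method = "pearson")
  # t approximation applied to the coefficient itself
  r <- 0.35; n <- 32
  p_expected <- 2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  expect_lt(abs(p_expected - 0.052), 0.005)
  expect_error(correlate(1:5, rep(1, 5)), "zero-variance")
  # Bonferroni flags use the family size
  z <- make_exact_cor(32, matrix(c(1, 0.4, 0.4, 1), 2), seed = 6)
  c6 <- correlate(z[, 1], z[, 2], family_size = 6)
  expect_equal(c6$bonferroni_threshold, 0.05 / 6)
  expect_true(c6$significant_raw)
  expect_false(c6$significant_bonferroni)
})

test_that("standard major axis fits are symmetric and equivariant", {
  x <- 1:10
  f <- sma_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  xt <- c(1, 2, 3, 4); yt <- c(1.1, 1.9, 3.2, 3.8)
  ft <- sma_fit(xt, yt)
  expect_equal(ft$slope, sign(stats::cor(xt, yt)) * stats::sd(yt) / stats::sd(xt))
  # swapping axes inverts the slope
  g <- sma_fit(yt, xt)
  expect_equal(ft$slope * g$slope, 1, tolerance = 1e-12)
  # rescaling y rescales the slope exactly
  f3 <- sma_fit(xt, 3 * yt)
  expect_equal(f3$slope, 3 * ft$slope)
  expect_error(sma_fit(rep(1, 5), 1:5), "non-constant")
})

test_that("signed-rank Z agrees with exact enumeration at n = 8", {
  exact_two_sided <- function(d) {
    rk <- rank(abs(d))
    t_obs <- sum(rk[d > 0])
    n <- length(d)
    signs <- expand.grid(rep(list(c(0, 1)), n))
    tstats <- as.matrix(signs) %*% rk
    mu <- n * (n + 1) / 4
    mean(abs(tstats - mu) >= abs(t_obs - mu) - 1e-9)
  }
  withr::with_seed(6, {
    for (i in 1:20) {
      x <- stats::rnorm(8, 0.4)
      y <- stats::rnorm(8)
      w <- wilcoxon_signed_rank(x, y)
      expect_lt(abs(w$p - exact_two_sided(x - y)), 0.03)
    }
  })
})

test_that("signed-rank Z hits its one-sided maximum and null midpoint", {
  n <- 32
  # all-positive, untied differences: maximal statistic for that n
  w <- wilcoxon_signed_rank((1:n) + seq(2, 3, length.out = n),
                            as.numeric(1:n))
  z_max <- (n * (n + 1) / 4 - 0.5) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(w$Z, z_max, tolerance = 1e-12)
  # at n = 38 the maximum is the study's 5.37
  w38 <- wilcoxon_signed_rank((1:38) + seq(2, 3, length.out = 38),
                              as.numeric(1:38))
  expect_equal(round(w38$Z, 2), 5.37)
  # antisymmetric differences cancel
  d <- c(rep(2, 10), rep(-2, 10))
  wa <- wilcoxon_signed_rank(d, rep(0, 20))
  expect_equal(wa$Z, 0, tolerance = 1e-12)
  expect_error(wilcoxon_signed_rank(rep(1, 10), rep(1, 10)), "non-zero")
})

test_that("signed-rank Z is invariant to monotone transforms of differences", {
  withr::with_seed(7, {
    x <- stats::rnorm(20, 0.5)
    y <- stats::rnorm(20)
    d <- x - y
    w1 <- wilcoxon_signed_rank(x, y)
    # a sign-preserving strictly monotone map keeps every rank
    d2 <- sign(d) * (abs(d)^3 + 1)
    w2 <- wilcoxon_signed_rank(d2, rep(0, 20))
    expect_equal(w1$Z, w2$Z, tolerance = 1e-12)
  })
})

test_that("balanced condition contrasts equal paired comparisons", {
  hi <- seq(0.9, 0.7, length.out = 10)
  lo <- hi - 0.2 + withr::with_seed(8, stats::rnorm(10, 0, 0.02))
  d <- data.frame(participant = rep(sprintf("P%02d", 1:10), 2),
                  condition = rep(c("ch16", "ch4"), each = 10),
                  mean_proportion = c(hi, lo))
  cc <- condition_contrasts(d, reference = "ch16")
  expect_equal(unname(cc$means["ch16"]), 0.8)
  expect_equal(cc$contrasts$difference, mean(lo - hi), tolerance = 1e-12)
  tt <- stats::t.test(lo, hi, paired = TRUE)
  expect_equal(cc$contrasts$t, unname(tt$statistic))
  # identical conditions: zero difference, zero t
  d2 <- d; d2$mean_proportion[d2$condition == "ch4"] <-
    d2$mean_proportion[d2$condition == "ch16"]
  cc2 <- condition_contrasts(d2, reference = "ch16")
  expect_equal(cc2$contrasts$difference, 0)
  expect_equal(cc2$contrasts$t, 0)
  # unbalanced data is refused
  expect_error(condition_contrasts(d[-1, ]), "drop incomplete")
})

test_that("correlation tables flag small cells and apply families", {
  pred <- data.frame(a = stats::rnorm(20), b = stats::rnorm(20))
  out <- data.frame(y = stats::rnorm(20))
  tab <- build_correlation_table(pred, out, method = "spearman")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "family_size"), 2)
  # a self-correlation cell reports 1
  tab2 <- build_correlation_table(data.frame(y = out$y), out)
  expect_equal(tab2$coefficient, 1)
  # too-few complete pairs: flagged missing, not computed
  pred$c <- c(1, 2, rep(NA, 18))
  tab3 <- build_correlation_table(pred["c"], out)
  expect_true(tab3$missing)
})
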