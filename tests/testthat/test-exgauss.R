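test_that("ex-Gaussian fits recover parameters and moment identities", {
  rt <- withr::with_seed(1, rexgauss(10000, 500, 50, 150))
  f <- fit_exgaussian(rt)
  expect_true(f$converged)
  expect_lt(abs(f$mu - 500) / 500, 0.05)
  expect_lt(abs(f$sigma - 50) / 50, 0.05)
  expect_lt(abs(f$tau - 150) / 150, 0.05)
  # E[X] = mu + tau, Var[X] = sigma^2 + tau^2
  expect_lt(abs((f$mu + f$tau) - mean(rt)) / mean(rt), 0.01)
  expect_lt(abs((f$sigma^2 + f$tau^2) - stats::var(rt)) / stats::var(rt),
            0.05)
})

test_that("a nearly Gaussian sample drives tau to the boundary", {
  rt <- withr::with_seed(2, stats::rnorm(2000, 500, 40))
  f <- fit_exgaussian(rt)
  expect_lt(abs((f$mu + f$tau) - mean(rt)) / mean(rt), 0.01)
  expect_lt(f$tau, 20)
})

test_that("the log-likelihood peaks at the fitted parameters", {
  rt <- withr::with_seed(3, rexgauss(5000, 500, 50, 150))
  f <- fit_exgaussian(rt)
  ll <- function(mu, sigma, tau) sum(dexgauss(rt, mu, sigma, tau, log = TRUE))
  base <- ll(f$mu, f$sigma, f$tau)
  expect_gte(base, ll(f$mu * 1.05, f$sigma, f$tau))
  expect_gte(base, ll(f$mu, f$sigma * 1.2, f$tau))
  expect_gte(base, ll(f$mu, f$sigma, f$tau * 1.2))
  expect_gte(base, ll(f$mu, f$sigma, f$tau * 0.8))
})

test_that("fitting guards its domain", {
  expect_error(fit_exgaussian(c(-1, rep(400, 100))), "positive")
  expect_error(fit_exgaussian(rep(400, 10)), "at least 50")
  expect_error(dexgauss(1, 0, -1, 1))
})

test_that("iterative trimming removes only the upper tail, to a fixed point", {
  expect_equal(trim_outliers(rep(400, 50))$n_removed, 0)
  # loop-free oracle for a two-pass case: one huge outlier masks a second
  x <- c(rep(400, 100), 700, 5000)
  # pass 1: mean 440.6, sd 458.3 -> threshold 2273.8 removes 5000
  # pass 2: mean 403.0, sd 29.8 -> threshold 522.3 removes 700
  # pass 3: all 400s, nothing above mean + 4*0 -> stop
  tr <- trim_outliers(x)
  expect_equal(tr$n_removed, 2)
  expect_true(all(tr$kept == 400))
  # symmetric low outlier is never removed
  y <- c(rep(400, 100), 5)
  expect_equal(trim_outliers(y)$n_removed, 0)
  expect_true(5 %in% trim_outliers(y)$kept)
  # output is always a subset, order preserved
  z <- withr::with_seed(4, rexgauss(500, 500, 50, 150))
  k <- trim_outliers(z)$kept
  expect_true(all(k %in% z))
  expect_identical(k, z[z %in% k])
})

test_that("geometric means behave as means of logs", {
  expect_equal(geometric_mean_rt(rep(400, 10)), 400)
  expect_equal(geometric_mean_rt(c(100, 10000)), 1000)
  withr::with_seed(5, {
    for (i in 1:50) {
      x <- stats::runif(20, 100, 2000)
      expect_lte(geometric_mean_rt(x), mean(x))
    }
  })
  expect_error(geometric_mean_rt(c(100, 0)), "positive")
})
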