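# Ex-Gaussian reaction-time model: the convolution of a Gaussian
# (mu, sigma) with an exponential (tau). The Gaussian component captures
# the central tendency of response times, the exponential the long slow
# tail; the distribution mean is mu + tau and the variance sigma^2 + tau^2.

#' Ex-Gaussian density and random generation
#'
#' @param x quantiles (ms).
#' @param n number of draws.
#' @param mu,sigma Gaussian component mean and SD (ms); `sigma > 0`.
#' @param tau exponential tail mean (ms); `tau > 0`.
#' @param log logical; return log density.
#' @return `dexgauss` returns (log) densities, `rexgauss` random deviates.
#' @export
#' @examples
#' dexgauss(600, mu = 500, sigma = 50, tau = 150)
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  stopifnot(sigma > 0, tau > 0)
  z <- (x - mu) / sigma
  # log f = -log(tau) + (sigma^2/(2 tau^2) - (x-mu)/tau) + log Phi(z - sigma/tau)
  lf <- -base::log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm(z - sigma / tau, log.p = TRUE)
  if (log) lf else exp(lf)
}

#' @rdname dexgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  stopifnot(sigma > 0, tau > 0)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}

#' Fit an ex-Gaussian distribution to reaction times
#'
#' Maximum-likelihood fit of (mu, sigma, tau) by bounded quasi-Newton
#' (L-BFGS-B) on the exact log density, initialized from the method of
#' moments: tau0 is the cube root of half the third central moment
#' (bounded below at 1 ms), mu0 = mean - tau0, and
#' sigma0^2 = max(variance - tau0^2, 1). Non-convergence is reported in
#' the `converged` flag, not raised as an error.
#'
#' @param rts positive reaction times in ms; at least 50 observations are
#'   required for a stable tail estimate.
#' @param min_n minimum number of observations (default 50).
#' @param lower lower bound for sigma and tau in ms (default 0.5).
#' @return object of class `exgauss_fit` with components `mu`, `sigma`,
#'   `tau`, `log_likelihood`, `converged`, `n`.
#' @export
#' @examples
#' rt <- rexgauss(500, 500, 50, 150)
#' fit_exgaussian(rt)
fit_exgaussian <- function(rts, min_n = 50, lower = 0.5) {
  if (any(!is.finite(rts)) || any(rts <= 0)) {
    stop_domain("reaction times must be positive and finite")
  }
  if (length(rts) < min_n) {
    stop_domain(sprintf("at least %d observations are required (got %d)",
                        min_n, length(rts)))
  }
  m <- mean(rts)
  v <- stats::var(rts)
  m3 <- mean((rts - m)^3)
  tau0 <- max((max(m3, 0) / 2)^(1 / 3), 1)
  mu0 <- m - tau0
  sigma0 <- sqrt(max(v - tau0^2, 1))
  nll <- function(p) -sum(dexgauss(rts, p[1], p[2], p[3], log = TRUE))
  opt <- stats::optim(c(mu0, sigma0, tau0), nll, method = "L-BFGS-B",
                      lower = c(-Inf, lower, lower),
                      control = list(maxit = 500))
  structure(list(mu = opt$par[1], sigma = opt$par[2], tau = opt$par[3],
                 log_likelihood = -opt$value,
                 converged = opt$convergence == 0,
                 n = length(rts)),
            class = "exgauss_fit")
}

#' @export
print.exgauss_fit <- function(x, ...) {
  cat(sprintf("ex-Gaussian fit (n = %d%s)\n", x$n,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  mu = %.1f ms, sigma = %.1f ms, tau = %.1f ms\n",
              x$mu, x$sigma, x$tau))
  cat(sprintf("  implied mean %.1f ms, SD %.1f ms; logLik %.1f\n",
              x$mu + x$tau, sqrt(x$sigma^2 + x$tau^2), x$log_likelihood))
  invisible(x)
}

#' @export
coef.exgauss_fit <- function(object, ...) {
  c(mu = object$mu, sigma = object$sigma, tau = object$tau)
}

#' @export
logLik.exgauss_fit <- function(object, ...) {
  structure(object$log_likelihood, df = 3, nobs = object$n,
            class = "logLik")
}

#' @export
simulate.exgauss_fit <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() rexgauss(nsim, object$mu, object$sigma, object$tau)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Iteratively trim slow reaction-time outliers
#'
#' Repeatedly removes all values more than `k` sample SDs above the
#' current mean until no value exceeds the threshold. Only the upper tail
#' is trimmed, matching the idea that contaminant RTs are slow lapses,
#' not fast guesses.
#'
#' @param rts reaction times in ms (at least 10).
#' @param k SD multiplier (default 4).
#' @return list with `kept` (the retained values, original order) and
#'   `n_removed`.
#' @export
#' @examples
#' trim_outliers(c(rep(400, 50), 5000))
trim_outliers <- function(rts, k = 4) {
  if (length(rts) < 10) stop_domain("at least 10 observations are required")
  kept <- rts
  repeat {
    thr <- mean(kept) + k * stats::sd(kept)
    if (is.na(thr)) break  # zero-variance guard (sd of length-1)
    drop <- kept > thr
    if (!any(drop)) break
    kept <- kept[!drop]
  }
  list(kept = kept, n_removed = length(rts) - length(kept))
}

#' Geometric mean reaction time
#'
#' @param rts positive reaction times in ms.
#' @return exp(mean(log(rts))), in ms.
#' @export
#' @examples
#' geometric_mean_rt(c(100, 10000))  # 1000
geometric_mean_rt <- function(rts) {
  if (length(rts) == 0 || any(!is.finite(rts)) || any(rts <= 0)) {
    stop_domain("reaction times must be positive and finite")
  }
  exp(mean(base::log(rts)))
}
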