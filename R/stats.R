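# Individual-differences statistics: principal-component composites with
# the eigenvalue retention rule, correlation cells with Bonferroni
# families, standard major axis regression, tie-corrected Wilcoxon
# signed-rank Z, balanced within-participant condition contrasts, and the
# correlation-table builders used for the attention analyses.

#' Principal-component composite of an accuracy matrix
#'
#' Eigendecomposition of the correlation matrix of a participants x
#' conditions accuracy table. Loadings are unit-norm eigenvectors with
#' signs fixed so every component has a positive mean loading; scores are
#' the standardized data projected on the loadings. Components with an
#' eigenvalue above 1 are retained by default, the conventional rule for
#' deciding how many composite scores to keep.
#'
#' @param accuracy_table numeric matrix or data.frame, participants in
#'   rows, conditions in columns; no missing cells, more rows than
#'   columns.
#' @param standardize logical; standardize columns (correlation-matrix
#'   analysis, default TRUE). With FALSE the covariance matrix is used.
#' @param retain optional integer vector of component indices to retain,
#'   overriding the eigenvalue > 1 rule.
#' @return object of class `pca_composite`: `loadings` (variables x
#'   components), `eigenvalues`, `variance_explained` (fractions summing
#'   to 1), `scores` (participants x components), `retained`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(90), 30, 3); x[, 2] <- x[, 1] + rnorm(30, sd = .5)
#' pca_composite(x)
pca_composite <- function(accuracy_table, standardize = TRUE,
                         retain = NULL) {
  x <- as.matrix(accuracy_table)
  if (anyNA(x)) stop_domain("accuracy table has missing cells")
  if (ncol(x) < 2) stop_domain("at least two columns are required")
  if (nrow(x) <= ncol(x)) {
    stop_domain("more participants than conditions are required")
  }
  sds <- apply(x, 2, stats::sd)
  const <- which(sds == 0)
  if (length(const)) {
    nm <- colnames(x)[const] %||% as.character(const)
    stop_domain("zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  xs <- scale(x, center = TRUE, scale = standardize)
  cm <- if (standardize) stats::cor(x) else stats::cov(x)
  eg <- eigen(cm, symmetric = TRUE)
  loadings <- eg$vectors
  # sign convention: positive mean loading on every component (ties by
  # the first non-zero loading)
  for (j in seq_len(ncol(loadings))) {
    s <- sign(mean(loadings[, j]))
    if (s == 0) s <- sign(loadings[which(loadings[, j] != 0)[1], j])
    loadings[, j] <- loadings[, j] * s
  }
  rownames(loadings) <- colnames(x)
  scores <- xs %*% loadings
  ev <- eg$values
  retained <- if (is.null(retain)) which(ev > 1) else as.integer(retain)
  structure(list(loadings = loadings, eigenvalues = ev,
                 variance_explained = ev / sum(ev), scores = scores,
                 retained = retained, standardize = standardize),
            class = "pca_composite")
}

#' @export
print.pca_composite <- function(x, digits = 2, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("Principal-component composite (%d variables)\n",
              nrow(x$loadings)))
  tab <- rbind(round(x$loadings, digits),
               Eigenvalue = round(x$eigenvalues, digits),
               `Variance explained` = paste0(
                 round(100 * x$variance_explained), "%"))
  colnames(tab) <- paste0("C", seq_len(k))
  print(tab, quote = FALSE)
  cat("Retained (eigenvalue > 1 unless overridden):",
      paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.pca_composite <- function(object, newdata, ...) {
  as.matrix(newdata) %*% object$loadings
}

#' Correlation cell with Bonferroni family flag
#'
#' Pearson or Spearman correlation with a two-sided p value from the t
#' approximation, plus significance flags at the raw 0.05 level and after
#' Bonferroni correction for a caller-specified family of tests. The
#' family size is always explicit: it is an analysis decision, never
#' inferred.
#'
#' @param x,y numeric vectors of equal length (>= 3), no missing values.
#' @param method `"pearson"` or `"spearman"`.
#' @param family_size number of tests in the Bonferroni family
#'   (default 1 = no correction).
#' @param labels optional character pair naming the variables.
#' @return object of class `correlation_cell`.
#' @export
#' @examples
#' correlate(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9), method = "spearman")
correlate <- function(x, y, method = c("pearson", "spearman"),
                      family_size = 1, labels = c("x", "y")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  if (anyNA(x) || anyNA(y)) {
    stop_domain("missing values: apply pairwise deletion upstream")
  }
  n <- length(x)
  if (n < 3) stop_domain("at least 3 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("zero-variance input")
  }
  r <- stats::cor(x, y, method = method)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  threshold <- 0.05 / family_size
  structure(list(pair = labels, method = method, coefficient = r,
                 p_value = p, n = n,
                 significant_raw = p < 0.05,
                 significant_bonferroni = p < threshold,
                 family_size = family_size,
                 bonferroni_threshold = threshold),
            class = "correlation_cell")
}

#' @export
print.correlation_cell <- function(x, ...) {
  stars <- if (x$significant_bonferroni) "**"
           else if (x$significant_raw) "*" else ""
  cat(sprintf("%s ~ %s: %s %s = %.3f, p = %.4g (n = %d)%s\n",
              x$pair[1], x$pair[2], x$method,
              if (x$method == "spearman") "rho" else "r",
              x$coefficient, x$p_value, x$n, stars))
  if (x$family_size > 1) {
    cat(sprintf("  Bonferroni family %d, threshold p < %.4f: %s\n",
                x$family_size, x$bonferroni_threshold,
                if (x$significant_bonferroni) "significant" else "ns"))
  }
  invisible(x)
}

#' Standard major axis regression
#'
#' Symmetric line fit for two variables that both carry error:
#' slope = sign(r) * sd(y) / sd(x), intercept through the means. Used for
#' the fitted lines in accuracy-accuracy scatter plots, where neither
#' variable is a predictor of the other.
#'
#' @param x,y numeric vectors; both non-constant, correlation non-zero.
#' @return list with `slope`, `intercept`, `r`.
#' @export
#' @examples
#' sma_fit(1:10, 2 * (1:10) + 1)
sma_fit <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("both variables must be non-constant")
  }
  r <- stats::cor(x, y)
  if (r == 0) stop_domain("zero correlation: SMA slope sign is undefined")
  slope <- sign(r) * stats::sd(y) / stats::sd(x)
  list(slope = slope, intercept = mean(y) - slope * mean(x), r = r)
}

#' Wilcoxon signed-rank test with normal approximation
#'
#' Classic paired signed-rank statistic: zero differences are dropped,
#' absolute differences are ranked with midranks for ties, and the Z
#' statistic uses the tie-corrected variance with a continuity
#' correction of one half toward the null (without it the normal
#' approximation is off by up to 0.07 at small n). The two-sided p comes
#' from the normal approximation.
#'
#' @param x,y paired numeric vectors.
#' @return list with `Z`, `p`, `n_used` (pairs after dropping zero
#'   differences), `W` (centred signed-rank statistic).
#' @export
#' @examples
#' wilcoxon_signed_rank(rnorm(20, 1), rnorm(20))
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y lengths differ")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 6) {
    stop_domain("at least 6 non-zero paired differences are required")
  }
  rk <- rank(abs(d))
  t_plus <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / 48
  v <- n * (n + 1) * (2 * n + 1) / 24 - tie_corr
  if (v <= 0) stop_domain("degenerate variance (all ranks tied)")
  dev <- t_plus - mu
  z <- if (dev == 0) 0 else (dev - 0.5 * sign(dev)) / sqrt(v)
  list(Z = z, p = 2 * stats::pnorm(-abs(z)), n_used = n, W = dev)
}

#' Within-participant condition contrasts for a balanced design
#'
#' For complete (every participant in every condition) accuracy data, the
#' fixed-effect condition estimates of a mixed model with a participant
#' random intercept equal the condition means, so this reports condition
#' means plus paired differences against a reference condition with
#' paired t statistics and two-sided p values.
#'
#' @param data data.frame with columns `participant`, `condition` and a
#'   value column.
#' @param value name of the value column (default `"mean_proportion"`).
#' @param reference reference condition label; default the condition with
#'   the most channels by natural string ordering, or the first level.
#' @return list with `means` (per condition) and `contrasts` (data.frame:
#'   condition, difference, t, df, p).
#' @export
condition_contrasts <- function(data, value = "mean_proportion",
                                reference = NULL) {
  stopifnot(all(c("participant", "condition", value) %in% names(data)))
  wide <- stats::reshape(
    data[, c("participant", "condition", value)],
    direction = "wide", idvar = "participant", timevar = "condition")
  if (anyNA(wide)) {
    stop_domain("unbalanced data: every participant needs every ",
                "condition; drop incomplete participants first")
  }
  conds <- sub(paste0("^", value, "\\."), "",
               setdiff(names(wide), "participant"))
  vals <- as.matrix(wide[, -1, drop = FALSE])
  colnames(vals) <- conds
  if (is.null(reference)) reference <- conds[1]
  if (!reference %in% conds) stop_domain("unknown reference condition")
  means <- colMeans(vals)
  others <- setdiff(conds, reference)
  contrasts <- do.call(rbind, lapply(others, function(cc) {
    d <- vals[, cc] - vals[, reference]
    if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)))) {
      # degenerate paired data: zero difference gives t = 0; a constant
      # non-zero difference is infinitely reliable
      tval <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      pval <- if (mean(d) == 0) 1 else 0
      return(data.frame(condition = cc, reference = reference,
                        difference = mean(d), t = tval,
                        df = length(d) - 1, p = pval,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(vals[, cc], vals[, reference], paired = TRUE)
    data.frame(condition = cc, reference = reference,
               difference = mean(d),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(means = means, contrasts = contrasts)
}

#' Build a predictor-by-outcome correlation table
#'
#' Computes one [correlate()] cell for every predictor/outcome pair with
#' a shared family size (default: the number of cells in the table, the
#' convention used for the attention-task tables). Pairs with fewer than
#' 3 complete observations are flagged missing rather than computed.
#'
#' @param predictors data.frame of predictor columns.
#' @param outcomes data.frame of outcome columns.
#' @param method correlation method for every cell.
#' @param family_size Bonferroni family; default `ncol(predictors) *
#'   ncol(outcomes)`.
#' @return data.frame with one row per cell: predictor, outcome,
#'   coefficient, p, n, significance flags.
#' @export
build_correlation_table <- function(predictors, outcomes,
                                    method = c("spearman", "pearson"),
                                    family_size = NULL) {
  method <- match.arg(method)
  if (is.null(family_size)) family_size <- ncol(predictors) * ncol(outcomes)
  rows <- list()
  for (p in names(predictors)) {
    for (o in names(outcomes)) {
      keep <- stats::complete.cases(predictors[[p]], outcomes[[o]])
      if (sum(keep) < 3) {
        rows[[length(rows) + 1L]] <- data.frame(
          predictor = p, outcome = o, coefficient = NA_real_,
          p_value = NA_real_, n = sum(keep), significant_raw = NA,
          significant_bonferroni = NA, missing = TRUE,
          stringsAsFactors = FALSE)
        next
      }
      cell <- correlate(predictors[[p]][keep], outcomes[[o]][keep],
                        method = method, family_size = family_size,
                        labels = c(p, o))
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, outcome = o, coefficient = cell$coefficient,
        p_value = cell$p_value, n = cell$n,
        significant_raw = cell$significant_raw,
        significant_bonferroni = cell$significant_bonferroni,
        missing = FALSE, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "method") <- method
  attr(out, "family_size") <- family_size
  out
}
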