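#' Rank-transform with average ties
#'
#' @param x numeric vector (length >= 2); NAs keep their place.
#' @return ranks in `[1, n]`, average ranks for ties.
#' @export
rank_transform <- function(x) {
  if (length(x) < 2L) stopf("rank_transform needs >= 2 values")
  rank(x, ties.method = "average", na.last = "keep")
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms `x` and `y`, residualizes each on an intercept plus the
#' covariates by least squares, and correlates the residuals. The p-value
#' uses the t approximation with `n - 2 - k` degrees of freedom.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix / data frame (n x k).
#' @return tibble with `rho`, `statistic`, `df`, `p_value`, `n`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  cov_m <- if (is.null(covariates)) NULL else as.matrix(covariates)
  keep <- stats::complete.cases(x, y, if (is.null(cov_m)) rep(0, length(x)) else cov_m)
  x <- x[keep]; y <- y[keep]
  if (!is.null(cov_m)) cov_m <- cov_m[keep, , drop = FALSE]
  n <- length(x)
  k <- if (is.null(cov_m)) 0L else ncol(cov_m)
  if (n <= k + 2L) stopf("partial_spearman needs n > #covariates + 2 (n = %d, k = %d)", n, k)
  rx <- rank_transform(x); ry <- rank_transform(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stopf("Constant variable after rank transformation")
  }
  X <- cbind(rep(1, n), cov_m)
  Q <- qr.Q(qr(X))
  res_x <- rx - Q %*% crossprod(Q, rx)
  res_y <- ry - Q %*% crossprod(Q, ry)
  # a variable fully explained by the covariates carries no partial signal
  if (stats::sd(res_x) < 1e-8 * stats::sd(rx) ||
      stats::sd(res_y) < 1e-8 * stats::sd(ry)) {
    return(tibble::tibble(rho = 0, statistic = 0, df = n - 2L - k,
                          p_value = 1, n = n))
  }
  rho <- as.numeric(stats::cor(res_x, res_y))
  df <- n - 2L - k
  tval <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  tibble::tibble(rho = rho, statistic = tval, df = df,
                 p_value = 2 * stats::pt(-abs(tval), df), n = n)
}

#' Nested-model F-test with partial R-squared
#'
#' Compares a full linear model against a nested null model (both get an
#' intercept): `F = [(RSS0 - RSS1)/(p1 - p0)] / [RSS1/(n - p1 - 1)]`,
#' partial `R^2 = (RSS0 - RSS1)/RSS0`, with the Ezekiel-style adjustment
#' `1 - (1 - R2) (n - p0 - 1)/(n - p1 - 1)`.
#'
#' @param y response vector.
#' @param x_null n x p0 matrix of nuisance regressors (NULL for intercept
#'   only); must be a column subset of the full model.
#' @param x_full n x p1 matrix adding the regressors under test.
#' @return one-row tibble: `statistic`, `df1`, `df2`, `p_value`,
#'   `partial_r2`, `adj_partial_r2`, `rss_null`, `rss_full`, `n`.
#' @export
nested_f_test <- function(y, x_null, x_full) {
  n <- length(y)
  X0 <- cbind(rep(1, n), x_null)
  X1 <- cbind(rep(1, n), x_full)
  p0 <- ncol(X0) - 1L; p1 <- ncol(X1) - 1L
  if (p1 <= p0) stopf("Full model must add regressors beyond the null model")
  if (n <= p1 + 1L) stopf("Need n > p1 + 1 (n = %d, p1 = %d)", n, p1)
  if (!is.null(colnames(x_null)) && !is.null(colnames(x_full)) &&
      !all(colnames(x_null) %in% colnames(x_full))) {
    stopf("x_null columns must be a subset of x_full columns")
  }
  q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    cols <- colnames(X1) %||% as.character(seq_len(ncol(X1)))
    dropped <- cols[setdiff(seq_len(ncol(X1)), q1$pivot[seq_len(q1$rank)])]
    stopf("Full design matrix is rank-deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  rss0 <- sum(stats::lm.fit(X0, y)$residuals^2)
  rss1 <- sum(qr.resid(q1, y)^2)
  df1 <- p1 - p0
  df2 <- n - p1 - 1L
  partial_r2 <- (rss0 - rss1) / rss0
  adj <- 1 - (1 - partial_r2) * (n - p0 - 1L) / (n - p1 - 1L)
  if (rss1 <= max(1e-12 * rss0, 1e-300)) {
    f <- Inf; p <- 0; partial_r2 <- 1; adj <- 1
  } else {
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  tibble::tibble(statistic = f, df1 = df1, df2 = df2, p_value = p,
                 partial_r2 = partial_r2, adj_partial_r2 = adj,
                 rss_null = rss0, rss_full = rss1, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Two-sided Mann-Whitney U test
#'
#' Exact enumeration for small untied samples (both n <= 8), otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param a,b numeric samples.
#' @return tibble with `u` (U statistic for `a`) and `p_value`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stopf("Both samples must be non-empty")
  exact <- length(a) <= 8L && length(b) <= 8L && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  tibble::tibble(u = unname(wt$statistic), p_value = wt$p.value)
}

#' One-way MANOVA with Pillai's trace
#'
#' @param groups list of n_g x p parameter matrices, one per group.
#' @return tibble with `pillai`, `statistic` (approximate F), `df1`, `df2`,
#'   `p_value`.
#' @export
manova_oneway <- function(groups) {
  if (length(groups) < 2L) stopf("Need at least 2 groups")
  p <- ncol(groups[[1]])
  if (any(vapply(groups, nrow, integer(1)) <= p)) {
    stopf("Each group needs more observations than parameters (p = %d)", p)
  }
  Y <- do.call(rbind, lapply(groups, as.matrix))
  g <- factor(rep(seq_along(groups), vapply(groups, nrow, integer(1))))
  fit <- stats::manova(Y ~ g)
  sm <- tryCatch(summary(fit, test = "Pillai")$stats,
                 error = function(e) stopf(
                   "MANOVA failed (%s); the within-group SSCP may be singular - reduce the parameter set",
                   conditionMessage(e)))
  tibble::tibble(pillai = sm[1, "Pillai"], statistic = sm[1, "approx F"],
                 df1 = sm[1, "num Df"], df2 = sm[1, "den Df"],
                 p_value = sm[1, "Pr(>F)"])
}

#' Calinski-Harabasz clusterability of a 1D gradient
#'
#' k-means (Lloyd) with deterministic quantile initialization (centers at
#' the 1/(2k), 3/(2k), ... quantiles; for k = 2 the quartiles), then
#' `CH = [B/(k - 1)] / [W/(n - k)]` from the between- and within-cluster
#' sums of squares. Invariant to affine rescaling of the values.
#'
#' @param values numeric gradient values.
#' @param k number of clusters (default 2, rostral vs caudal).
#' @return scalar CH index.
#' @export
calinski_harabasz <- function(values, k = 2L) {
  values <- as.numeric(values)
  n <- length(values)
  if (length(unique(values)) < 2L * k) {
    stopf("Calinski-Harabasz needs >= 2k distinct values (k = %d)", k)
  }
  centers <- stats::quantile(values, probs = (2 * seq_len(k) - 1) / (2 * k),
                             names = FALSE, type = 7)
  if (any(duplicated(centers))) centers <- sort(unique(values))[round(seq(1, length(unique(values)), length.out = k))]
  km <- stats::kmeans(matrix(values, ncol = 1), centers = matrix(centers, ncol = 1),
                      iter.max = 100L, algorithm = "Lloyd")
  B <- km$betweenss
  W <- km$tot.withinss
  (B / (k - 1)) / (W / (n - k))
}
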