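tsm_terms <- c("x", "y", "z", "x2", "y2", "z2", "x3", "y3", "z3")

#' Third-order trend-surface basis for one hemisphere
#'
#' Nine pure-power spatial regressors `x, y, z, x^2, y^2, z^2, x^3, y^3,
#' z^3` built from per-hemisphere z-scored world coordinates (no
#' cross-terms). For left/right comparability the left hemisphere's
#' medio-lateral axis is sign-flipped before z-scoring so "lateral" is
#' positive on both sides. The intercept is handled separately by the fit.
#'
#' @param coords a [coordinate_table()].
#' @param hemisphere `"left"` or `"right"`.
#' @return voxels x 9 matrix with fixed column order and attributes
#'   `center`/`scale` (the z-scoring parameters) and `rows` (coordinate
#'   table row indices used).
#' @export
tsm_basis <- function(coords, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  rows <- which(coords$hemisphere == hemisphere)
  if (length(rows) < 10L) {
    stopf("Hemisphere %s has %d voxels; >= 10 required for a 9-term basis",
          hemisphere, length(rows))
  }
  xyz <- as.matrix(coords[rows, c("x", "y", "z")])
  if (hemisphere == "left") xyz[, 1] <- -xyz[, 1]   # lateral positive on both sides
  ctr <- colMeans(xyz)
  scl <- apply(xyz, 2, stats::sd)
  flat <- scl < .Machine$double.eps
  if (any(flat)) {
    stopf("Axis with zero spatial variance in %s hemisphere: %s",
          hemisphere, paste(c("x", "y", "z")[flat], collapse = ", "))
  }
  zs <- sweep(sweep(xyz, 2, ctr), 2, scl, "/")
  B <- cbind(zs, zs^2, zs^3)
  colnames(B) <- tsm_terms
  attr(B, "center") <- ctr
  attr(B, "scale") <- scl
  attr(B, "rows") <- rows
  attr(B, "hemisphere") <- hemisphere
  B
}

#' Fit a third-order trend-surface model by Bayesian ridge regression
#'
#' Empirical-Bayes Gaussian linear model: conjugate zero-mean isotropic
#' prior on the 9 spatial coefficients (intercept unpenalized), with prior
#' precision `alpha` and noise precision `beta` set by evidence
#' maximization (fixed-point iteration on the effective degrees of
#' freedom). For strong data the posterior mean reduces to least squares;
#' the fit is deterministic.
#'
#' @param values gradient values, one per basis row.
#' @param basis a [tsm_basis()].
#' @param max_iter,tol fixed-point iteration controls (convergence when
#'   successive `alpha` change falls below `tol`).
#' @return An object of class `tsm_fit`: `coefficients` (9, named),
#'   `intercept`, `alpha`, `beta`, `r_squared`, `converged`, `n_iter`,
#'   `log_evidence` (per-iteration trace), `hemisphere`.
#' @export
fit_tsm <- function(values, basis, max_iter = 200L, tol = 1e-6) {
  B <- unclass(basis)
  if (length(values) != nrow(B)) stopf("values must match the basis rows (%d vs %d)", length(values), nrow(B))
  n <- nrow(B); p <- ncol(B)
  ybar <- mean(values)
  yc <- values - ybar
  xctr <- colMeans(B)
  Xc <- sweep(B, 2, xctr)
  sv <- svd(Xc)
  d2 <- sv$d^2
  uty <- crossprod(sv$u, yc)       # length min(n, p)
  yty <- sum(yc^2)

  alpha <- 1
  beta <- if (stats::var(values) > 0) 1 / stats::var(values) else 1
  converged <- FALSE
  log_ev <- numeric(0)
  m_rot <- NULL
  for (it in seq_len(max_iter)) {
    denom <- alpha + beta * d2
    m_rot <- beta * d2^0.5 * uty / denom      # coefficients in the SVD basis (V frame)
    # residual sum of squares: yc - X m, computed in the rotated frame
    fit_rot <- beta * d2 * uty / denom
    rss <- yty - 2 * sum(uty * fit_rot) + sum(fit_rot^2)
    gamma_eff <- sum(beta * d2 / denom)
    m2 <- sum(m_rot^2)
    log_ev <- c(log_ev, 0.5 * (p * log(alpha) + n * log(beta) -
                                 beta * rss - alpha * m2 -
                                 sum(log(denom)) - n * log(2 * pi)))
    alpha_new <- if (m2 > 1e-12) gamma_eff / m2 else 1e10
    beta_new <- if (rss > 1e-12) (n - gamma_eff) / rss else 1e10
    delta <- abs(alpha_new - alpha)
    alpha <- alpha_new; beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  denom <- alpha + beta * d2
  coef_v <- sv$v %*% (beta * sv$d * uty / denom)
  coefficients <- stats::setNames(as.vector(coef_v), colnames(B))
  intercept <- ybar - sum(xctr * coefficients)
  fitted <- as.vector(Xc %*% coefficients) + ybar
  tss <- sum((values - ybar)^2)
  r2 <- if (tss > 0) 1 - sum((values - fitted)^2) / tss else NA_real_
  structure(list(coefficients = coefficients, intercept = intercept,
                 alpha = alpha, beta = beta, r_squared = r2,
                 converged = converged, n_iter = length(log_ev),
                 log_evidence = log_ev,
                 hemisphere = attr(basis, "hemisphere") %||% NA_character_),
            class = "tsm_fit")
}

#' @export
print.tsm_fit <- function(x, ...) {
  cat(sprintf("<tsm_fit> %s hemisphere, R^2 = %.3f, alpha = %.3g, converged: %s\n",
              x$hemisphere, x$r_squared, x$alpha, x$converged))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.tsm_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
                 hemisphere = x$hemisphere)
}

#' @export
glance.tsm_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, alpha = x$alpha, beta = x$beta,
                 intercept = x$intercept, converged = x$converged,
                 n_iter = x$n_iter, hemisphere = x$hemisphere)
}

#' Bilateral trend-surface fit of a gradient
#'
#' Builds an independent basis and Bayesian ridge fit per hemisphere.
#'
#' @param gradient a `gradient_map` (or numeric values aligned to `coords`).
#' @param coords coordinate table (taken from the gradient if omitted).
#' @return list of class `tsm_bilateral` with elements `left` and `right`.
#' @export
fit_bilateral <- function(gradient, coords = NULL) {
  if (inherits(gradient, "gradient_map")) {
    coords <- coords %||% gradient$coords
    values <- gradient$values
  } else {
    values <- gradient
  }
  if (is.null(coords)) stopf("coords required when gradient is a plain vector")
  fits <- lapply(stats::setNames(c("left", "right"), c("left", "right")), function(h) {
    B <- tsm_basis(coords, h)
    fit_tsm(values[attr(B, "rows")], B)
  })
  structure(fits, class = "tsm_bilateral")
}

#' @export
tidy.tsm_bilateral <- function(x, ...) {
  dplyr::bind_rows(tidy(x$left), tidy(x$right))
}

# Flat named vector of the 18 bilateral spatial coefficients
# (left_x ... left_z3, right_x ... right_z3); downstream statistics
# consume exactly these, the intercepts are excluded.
bilateral_params <- function(fits) {
  c(stats::setNames(fits$left$coefficients, paste0("left_", tsm_terms)),
    stats::setNames(fits$right$coefficients, paste0("right_", tsm_terms)))
}

#' Left-right asymmetry of two trend-surface fits
#'
#' Entrywise absolute coefficient differences and their Euclidean norm, a
#' scalar asymmetry index that is zero iff the two coefficient vectors are
#' equal.
#'
#' @param left,right `tsm_fit` objects on the same basis convention, or a
#'   `tsm_bilateral` as `left` with `right` missing.
#' @return list of class `asymmetry_profile`: `per_parameter` (9 named
#'   nonnegative values) and `index`.
#' @export
tsm_asymmetry <- function(left, right = NULL) {
  if (inherits(left, "tsm_bilateral")) {
    right <- left$right; left <- left$left
  }
  d <- abs(left$coefficients - right$coefficients)
  structure(list(per_parameter = d, index = sqrt(sum(d^2))),
            class = "asymmetry_profile")
}

#' @export
print.asymmetry_profile <- function(x, ...) {
  cat(sprintf("<asymmetry_profile> index = %.4f\n", x$index))
  print(round(x$per_parameter, 4))
  invisible(x)
}

#' Export trend-surface fits as a tidy table
#'
#' One row per (unit, hemisphere) with the 9 coefficient columns named
#' `bx, by, bz, bx2, ..., bz3`, the intercept and the convergence flag.
#'
#' @param fits list of `tsm_bilateral` objects (e.g. one per subject or
#'   window).
#' @param ids optional identifiers (defaults to list index).
#' @return tibble.
#' @export
tsm_table <- function(fits, ids = NULL) {
  ids <- ids %||% seq_along(fits)
  purrr::map2_dfr(fits, ids, function(f, id) {
    purrr::map_dfr(c("left", "right"), function(h) {
      cf <- as.list(stats::setNames(f[[h]]$coefficients, paste0("b", tsm_terms)))
      tibble::tibble(id = id, hemisphere = h, !!!cf,
                     intercept = f[[h]]$intercept, converged = f[[h]]$converged)
    })
  })
}
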