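#' Sliding windows over subjects sorted by a score
#'
#' Sorts records by the score (ties broken by `id` for determinism), then
#' forms windows of `window_length` consecutive subjects advanced by
#' `step`. Trailing subjects not covered by a full window are dropped with
#' a message. Window count is `floor((n - window_length)/step) + 1`.
#'
#' @param data tibble with at least `id` and the score column.
#' @param score column name (string) to sort by; rows with missing score
#'   are removed first.
#' @param window_length,step window size and stride in subjects.
#' @return tibble with one row per window: `window`, `start`, `members`
#'   (list of row indices into the sorted data), `ids` (list), and the
#'   window-mean score column.
#' @export
sliding_windows <- function(data, score, window_length = 20L, step = 5L) {
  data <- dplyr::filter(data, !is.na(.data[[score]]))
  n <- nrow(data)
  if (n < window_length) {
    stopf("Need at least window_length = %d subjects with non-missing %s (got %d)",
          window_length, score, n)
  }
  ord <- order(data[[score]], data$id)
  sorted <- data[ord, ]
  n_windows <- (n - window_length) %/% step + 1L
  dropped <- n - ((n_windows - 1L) * step + window_length)
  if (dropped > 0L) {
    message(sprintf("sliding_windows: %d trailing subject(s) not covered by a full window", dropped))
  }
  starts <- (seq_len(n_windows) - 1L) * step + 1L
  members <- lapply(starts, function(s) seq(s, s + window_length - 1L))
  out <- tibble::tibble(
    window = seq_len(n_windows),
    start = starts,
    members = members,
    ids = lapply(members, function(m) sorted$id[m]),
    score_mean = vapply(members, function(m) mean(sorted[[score]][m]), numeric(1))
  )
  attr(out, "sorted") <- sorted
  out
}

# Window gradients -> bilateral TSM parameter matrix (windows x 18),
# plus the per-window mean of the requested covariate columns.
window_parameters <- function(cohort, windows, sorted, covariates) {
  sims <- cohort$sims
  id_index <- stats::setNames(seq_len(nrow(cohort$covariates)), cohort$covariates$id)
  params <- matrix(NA_real_, nrow(windows), 18L)
  fits <- vector("list", nrow(windows))
  cov_means <- matrix(NA_real_, nrow(windows), length(covariates),
                      dimnames = list(NULL, covariates))
  for (w in seq_len(nrow(windows))) {
    subj <- id_index[windows$ids[[w]]]
    grad <- group_gradient(sims[subj], cohort$coords, cohort$exclude %||% integer(0))
    fits[[w]] <- fit_bilateral(grad)
    params[w, ] <- bilateral_params(fits[[w]])
    for (cv in covariates) {
      cov_means[w, cv] <- mean(sorted[[cv]][windows$members[[w]]])
    }
  }
  colnames(params) <- names(bilateral_params(fits[[1]]))
  list(params = params, cov_means = cov_means, fits = fits)
}

#' Sliding-window behavioral analysis
#'
#' Reproduces the sliding-window procedure: subjects are sorted by the
#' behavioral score, a group gradient and bilateral trend-surface fit are
#' computed for each window of `window_length` subjects (stride `step`),
#' and the window-mean score is regressed on the 18 spatial parameters
#' over and above the window-mean nuisance covariates (nested F-test with
#' adjusted partial R-squared). Post hoc, each parameter's partial
#' Spearman correlation with the score (controlling the same covariates)
#' is computed and Benjamini-Hochberg adjusted across the 18 parameters.
#'
#' @param cohort an `lc_cohort`.
#' @param score score column name (e.g. `"em_recognition"`).
#' @param covariates nuisance covariate columns (window means are used).
#' @param window_length,step window size and stride.
#' @param parameters optional subset of the 18 parameter names (e.g.
#'   `c("left_y", "right_y")`) to include as regressors; default all 18.
#' @return list of class `lc_window_analysis`: `f_test` (one-row tibble),
#'   `correlations` (per-parameter tibble with `rho`, `p_value`,
#'   `p_adjusted`), `windows`, `params`, `score`.
#' @export
window_behavior_analysis <- function(cohort, score,
                                     covariates = c("age", "sex", "education"),
                                     window_length = 20L, step = 5L,
                                     parameters = NULL) {
  data <- dplyr::filter(cohort$covariates,
                        stats::complete.cases(dplyr::pick(dplyr::all_of(c(score, covariates)))))
  windows <- sliding_windows(data, score, window_length, step)
  sorted <- attr(windows, "sorted")
  wp <- window_parameters(cohort, windows, sorted, covariates)
  params <- wp$params
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, colnames(params))
    if (length(missing)) stopf("Unknown parameter(s): %s", paste(missing, collapse = ", "))
    params <- params[, parameters, drop = FALSE]
  }
  n_win <- nrow(windows)
  p_full <- ncol(wp$cov_means) + ncol(params)
  if (n_win < p_full + 2L) {
    stopf("Only %d windows for %d regressors; increase n, reduce parameters, or shrink the window/step",
          n_win, p_full)
  }
  y <- windows$score_mean
  f_test <- nested_f_test(y, wp$cov_means, cbind(wp$cov_means, params))
  correlations <- purrr::map_dfr(colnames(params), function(pn) {
    ps <- partial_spearman(params[, pn], y, wp$cov_means)
    tibble::tibble(parameter = pn, rho = ps$rho, p_value = ps$p_value)
  })
  correlations$p_adjusted <- bh_fdr(correlations$p_value)
  structure(list(f_test = f_test, correlations = correlations,
                 windows = windows[, c("window", "start", "ids", "score_mean")],
                 params = params, cov_means = wp$cov_means, score = score),
            class = "lc_window_analysis")
}

#' @export
print.lc_window_analysis <- function(x, ...) {
  cat(sprintf("<lc_window_analysis> score: %s, %d windows\n", x$score, nrow(x$params)))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g, adjusted partial R^2 = %.3f\n",
              x$f_test$df1, x$f_test$df2, x$f_test$statistic, x$f_test$p_value,
              x$f_test$adj_partial_r2))
  invisible(x)
}

#' Per-year age analysis of group gradients
#'
#' Pools subjects into integer-year age bins, computes a group gradient
#' and bilateral trend-surface fit per bin, and tests whether the 18
#' spatial parameters explain variance in age (bin year) over and above
#' the bin-mean sex (nested F-test), plus per-parameter partial Spearman
#' correlations with age controlling sex, Benjamini-Hochberg adjusted.
#'
#' @param cohort an `lc_cohort`.
#' @param parameters optional subset of parameter names, as in
#'   [window_behavior_analysis()].
#' @return list of class `lc_age_analysis`: `f_test`, `correlations`,
#'   `bins` (tibble with year, n), `params`.
#' @export
per_year_age_analysis <- function(cohort, parameters = NULL) {
  cov_tab <- cohort$covariates
  year <- floor(cov_tab$age)
  bins <- sort(unique(year))
  if (length(bins) < 20L) {
    warnf("Only %d age bins; per-year analysis will have low power", length(bins))
  }
  params <- matrix(NA_real_, length(bins), 18L)
  sex_mean <- numeric(length(bins))
  n_bin <- integer(length(bins))
  for (b in seq_along(bins)) {
    subj <- which(year == bins[b])
    n_bin[b] <- length(subj)
    grad <- group_gradient(cohort$sims[subj], cohort$coords, cohort$exclude %||% integer(0))
    params[b, ] <- bilateral_params(fit_bilateral(grad))
    sex_mean[b] <- mean(cov_tab$sex[subj])
  }
  colnames(params) <- c(paste0("left_", tsm_terms), paste0("right_", tsm_terms))
  if (!is.null(parameters)) params <- params[, parameters, drop = FALSE]
  x_null <- cbind(sex = sex_mean)
  f_test <- nested_f_test(bins, x_null, cbind(x_null, params))
  correlations <- purrr::map_dfr(colnames(params), function(pn) {
    ps <- partial_spearman(params[, pn], bins, x_null)
    tibble::tibble(parameter = pn, rho = ps$rho, p_value = ps$p_value)
  })
  correlations$p_adjusted <- bh_fdr(correlations$p_value)
  structure(list(f_test = f_test, correlations = correlations,
                 bins = tibble::tibble(year = bins, n = n_bin, sex_mean = sex_mean),
                 params = params),
            class = "lc_age_analysis")
}

#' @export
print.lc_age_analysis <- function(x, ...) {
  cat(sprintf("<lc_age_analysis> %d age bins\n", nrow(x$bins)))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g, adjusted partial R^2 = %.3f\n",
              x$f_test$df1, x$f_test$df2, x$f_test$statistic, x$f_test$p_value,
              x$f_test$adj_partial_r2))
  invisible(x)
}

#' Gradient clusterability versus age
#'
#' Computes each subject's own dominant gradient from its similarity
#' matrix, scores its clusterability with the Calinski-Harabasz criterion
#' (k-means, k = 2), and correlates clusterability with age by partial
#' Spearman correlation controlling sex.
#'
#' @param cohort an `lc_cohort`.
#' @param k number of clusters for the criterion.
#' @return list of class `lc_clusterability`: `subjects` (tibble with id,
#'   age, sex, ch), `rho`, `p_value`, `test` (full partial-Spearman row).
#' @export
clusterability_vs_age <- function(cohort, k = 2L) {
  n <- nrow(cohort$covariates)
  ch <- numeric(n)
  for (s in seq_len(n)) {
    grad <- roi_gradient(cohort$sims[[s]], cohort$coords, source = "subject",
                         exclude = cohort$exclude %||% integer(0))
    ch[s] <- calinski_harabasz(grad$values, k = k)
  }
  test <- partial_spearman(ch, cohort$covariates$age,
                           cbind(sex = cohort$covariates$sex))
  structure(list(subjects = tibble::tibble(id = cohort$covariates$id,
                                           age = cohort$covariates$age,
                                           sex = cohort$covariates$sex, ch = ch),
                 rho = test$rho, p_value = test$p_value, test = test),
            class = "lc_clusterability")
}

#' @export
print.lc_clusterability <- function(x, ...) {
  cat(sprintf("<lc_clusterability> n = %d, partial Spearman rho = %.3f, p = %.4g\n",
              nrow(x$subjects), x$rho, x$p_value))
  invisible(x)
}

#' Bootstrap MANOVA group comparison of gradient spatial parameters
#'
#' Stratifies subjects into two groups (by default normal vs abnormal
#' anxiety/depression screening score, `hads > 7`), then bootstraps equal
#' numbers of group-average gradients: per iteration and group, `draw`
#' subjects are sampled with replacement, their similarity matrices
#' averaged into a group gradient, and its 18 bilateral trend-surface
#' parameters recorded. The two collections of parameter vectors are
#' compared by one-way MANOVA (Pillai's trace) with per-parameter
#' Mann-Whitney U post hocs, Benjamini-Hochberg adjusted.
#'
#' @param cohort an `lc_cohort`.
#' @param groups either NULL (default HADS > 7 split) or a list of two id
#'   vectors. The two pools may overlap (useful for calibration checks).
#' @param draw subjects drawn per iteration.
#' @param iterations bootstrap iterations per group.
#' @param seed seed for the bootstrap draws.
#' @return list of class `lc_group_comparison`: `manova` (tibble),
#'   `posthoc` (per-parameter tibble with `u`, `p_value`, `p_adjusted`),
#'   `params` (list of the two iteration x 18 matrices), `group_sizes`.
#' @export
bootstrap_group_comparison <- function(cohort, groups = NULL, draw = 20L,
                                       iterations = 1000L, seed = 1L) {
  cov_tab <- cohort$covariates
  if (is.null(groups)) {
    if (!"hads" %in% names(cov_tab)) stopf("No `hads` column; supply `groups` explicitly")
    groups <- list(normal = cov_tab$id[!is.na(cov_tab$hads) & cov_tab$hads <= 7],
                   abnormal = cov_tab$id[!is.na(cov_tab$hads) & cov_tab$hads > 7])
  }
  sizes <- lengths(groups)
  small <- sizes < draw
  if (any(small)) {
    stopf("Group(s) smaller than draw = %d: %s", draw,
          paste(sprintf("%s (n = %d)", names(groups)[small] %||% which(small), sizes[small]),
                collapse = ", "))
  }
  id_index <- stats::setNames(seq_len(nrow(cov_tab)), cov_tab$id)
  params <- with_seed(seed, {
    lapply(groups, function(ids) {
      subj_pool <- id_index[ids]
      out <- matrix(NA_real_, iterations, 18L)
      for (it in seq_len(iterations)) {
        subj <- sample(subj_pool, draw, replace = TRUE)
        grad <- group_gradient(cohort$sims[subj], cohort$coords, cohort$exclude %||% integer(0))
        out[it, ] <- bilateral_params(fit_bilateral(grad))
      }
      colnames(out) <- c(paste0("left_", tsm_terms), paste0("right_", tsm_terms))
      out
    })
  })
  manova_res <- manova_oneway(params)
  posthoc <- purrr::map_dfr(colnames(params[[1]]), function(pn) {
    mw <- mann_whitney(params[[1]][, pn], params[[2]][, pn])
    tibble::tibble(parameter = pn, u = mw$u, p_value = mw$p_value)
  })
  posthoc$p_adjusted <- bh_fdr(posthoc$p_value)
  structure(list(manova = manova_res, posthoc = posthoc, params = params,
                 group_sizes = sizes, draw = draw, iterations = iterations,
                 seed = seed),
            class = "lc_group_comparison")
}

#' @export
print.lc_group_comparison <- function(x, ...) {
  cat(sprintf("<lc_group_comparison> groups n = %s, %d iterations of %d draws\n",
              paste(x$group_sizes, collapse = "/"), x$iterations, x$draw))
  cat(sprintf("  Pillai = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$manova$pillai, x$manova$df1, x$manova$df2,
              x$manova$statistic, x$manova$p_value))
  invisible(x)
}

#' @export
tidy.lc_window_analysis <- function(x, ...) x$correlations
#' @export
glance.lc_window_analysis <- function(x, ...) x$f_test
#' @export
tidy.lc_age_analysis <- function(x, ...) x$correlations
#' @export
glance.lc_age_analysis <- function(x, ...) x$f_test
#' @export
tidy.lc_group_comparison <- function(x, ...) x$posthoc
#' @export
glance.lc_group_comparison <- function(x, ...) x$manova
#' @export
tidy.lc_clusterability <- function(x, ...) x$subjects
#' @export
glance.lc_clusterability <- function(x, ...) x$test
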