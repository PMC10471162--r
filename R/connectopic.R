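#' Connectivity fingerprints
#'
#' Pearson correlation of every ROI voxel time series with every parcel
#' mean time series. Row order follows the coordinate table; columns follow
#' the parcel row order.
#'
#' @param roi_ts voxels x time matrix.
#' @param parcel_ts parcels x time matrix.
#' @return voxels x parcels correlation matrix.
#' @export
fingerprints <- function(roi_ts, parcel_ts) {
  if (ncol(roi_ts) != ncol(parcel_ts)) {
    stopf("ROI and parcel series must share the time axis (%d vs %d)",
          ncol(roi_ts), ncol(parcel_ts))
  }
  if (ncol(roi_ts) < 3L) stopf("Need >= 3 timepoints for correlations")
  pv <- matrixStats_rowVars(parcel_ts)
  if (any(pv < .Machine$double.eps)) {
    bad <- rownames(parcel_ts)[pv < .Machine$double.eps] %||%
      which(pv < .Machine$double.eps)
    stopf("Zero-variance parcel time series: %s", paste(bad, collapse = ", "))
  }
  vv <- matrixStats_rowVars(roi_ts)
  if (any(vv < .Machine$double.eps)) {
    stopf("Zero-variance ROI voxel series (handle upstream): voxel(s) %s",
          paste(which(vv < .Machine$double.eps), collapse = ", "))
  }
  stats::cor(t(roi_ts), t(parcel_ts))
}

#' Eta-squared similarity of two connectivity fingerprints
#'
#' `eta2 = 1 - sum_i[(a_i - m_i)^2 + (b_i - m_i)^2] /
#'             sum_i[(a_i - M)^2 + (b_i - M)^2]`
#' with `m_i = (a_i + b_i)/2` and `M` the grand mean of both profiles.
#' Always in `[0, 1]`, symmetric, and 1 for identical profiles.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return scalar similarity.
#' @export
eta_squared <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L) {
    stopf("fingerprint rows must have equal length >= 2")
  }
  m <- (a + b) / 2
  M <- mean(c(a, b))
  num <- sum((a - m)^2 + (b - m)^2)
  den <- sum((a - M)^2 + (b - M)^2)
  if (den <= .Machine$double.eps) {
    warnf("eta_squared: both profiles constant and identical; returning 1")
    return(1)
  }
  min(1, max(0, 1 - num / den))
}

#' Eta-squared similarity matrix of all voxel pairs
#'
#' Vectorized over all pairs of fingerprint rows; diagonal set to 1.
#'
#' @param fp voxels x parcels fingerprint matrix.
#' @return symmetric voxels x voxels matrix in `[0, 1]`.
#' @export
similarity_matrix <- function(fp) {
  fp <- as.matrix(fp)
  n <- nrow(fp); p <- ncol(fp)
  G <- tcrossprod(fp)               # sum_i a_i b_i
  sq <- diag(G)                     # sum_i a_i^2
  rm_ <- rowMeans(fp)
  # numerator*2 = |a-b|^2 ; denominator = SSa + SSb + p*(abar-bbar)^2/2
  d2 <- outer(sq, sq, "+") - 2 * G
  ss <- sq - p * rm_^2
  den <- outer(ss, ss, "+") + p * outer(rm_, rm_, "-")^2 / 2
  S <- 1 - (d2 / 2) / den
  S[den <= .Machine$double.eps] <- 1
  S[S < 0] <- 0; S[S > 1] <- 1
  S <- (S + t(S)) / 2
  diag(S) <- 1
  S
}

#' Maximal connectivity-preserving similarity graph
#'
#' Finds the largest threshold `t` (among the off-diagonal similarity
#' values, by binary search) such that the graph with edges
#' `eta2 >= t` is still a single connected component, then retains all
#' edges at or above it with their eta-squared weights.
#'
#' @param S symmetric similarity matrix.
#' @return list of class `similarity_graph`: `W` (weighted adjacency, zero
#'   diagonal), `degrees` (row sums), `threshold`.
#' @export
build_connected_graph <- function(S) {
  S <- as.matrix(S)
  n <- nrow(S)
  # The largest connectivity-preserving threshold is the bottleneck of the
  # maximum spanning tree: the graph with edges >= t is connected exactly
  # when t does not exceed the smallest edge on that tree (Prim, O(n^2)).
  thr <- if (n <= 1L) 1 else {
    intree <- logical(n)
    intree[1L] <- TRUE
    best <- S[, 1L]
    bn <- Inf
    for (k in seq_len(n - 1L)) {
      cand <- which(!intree)
      j <- cand[which.max(best[cand])]
      bn <- min(bn, best[j])
      intree[j] <- TRUE
      best <- pmax(best, S[, j])
    }
    bn
  }
  if (thr <= 0) {
    # only possible with exact zeros: fall back to all positive edges
    off <- S[upper.tri(S)]
    if (!adj_is_connected(S > 0 & upper_lower_mask(n))) {
      stopf("Similarity matrix yields a disconnected graph even with all positive edges")
    }
    thr <- min(off[off > 0])
  }
  W <- S
  W[W < thr] <- 0
  diag(W) <- 0
  structure(list(W = W, degrees = rowSums(W), threshold = thr),
            class = "similarity_graph")
}

upper_lower_mask <- function(n) {
  m <- matrix(TRUE, n, n); diag(m) <- FALSE; m
}

#' Laplacian eigenmap of a similarity graph
#'
#' Solves the generalized eigenproblem `(D - W) v = lambda D v` through the
#' symmetric normalized Laplacian and returns the `n_components`
#' eigenvectors of smallest nonzero eigenvalue (the trivial constant
#' solution at lambda = 0 is discarded). Eigenvectors are D-orthonormal;
#' the first is the dominant gradient.
#'
#' @param graph a [build_connected_graph()] result.
#' @param n_components number of nontrivial components to return.
#' @return list of class `eigen_system`: `values`, `vectors`,
#'   `lambda0` (the discarded trivial eigenvalue), `unstable` (TRUE when
#'   the two smallest nonzero eigenvalues are numerically tied).
#' @export
laplacian_eigenmap <- function(graph, n_components = 1L) {
  W <- graph$W
  d <- graph$degrees
  n <- nrow(W)
  if (n_components < 1L || n_components > n - 1L) {
    stopf("n_components must be in [1, %d]", n - 1L)
  }
  if (any(d <= 0)) stopf("Graph has isolated vertices; it must be connected")
  isd <- 1 / sqrt(d)
  Lsym <- diag(n) - (isd * W) * rep(isd, each = n)   # I - D^-1/2 W D^-1/2
  es <- eigen((Lsym + t(Lsym)) / 2, symmetric = TRUE)
  ord <- rev(seq_len(n))                             # ascending eigenvalues
  values <- pmax(es$values[ord], 0)
  vectors <- es$vectors[, ord, drop = FALSE] * isd   # v = D^-1/2 u
  if (es$values[ord][1] > 1e-8) {
    warnf("Smallest eigenvalue %.3g is not numerically zero; graph may be ill-conditioned",
          values[1])
  }
  unstable <- FALSE
  if (n >= 3L && abs(values[3] - values[2]) < 1e-10) {
    unstable <- TRUE
    warnf("Repeated smallest nonzero eigenvalue (gap %.3g); gradient direction unstable",
          abs(values[3] - values[2]))
  }
  keep <- 1L + seq_len(n_components)
  structure(list(values = values[keep], vectors = vectors[, keep, drop = FALSE],
                 lambda0 = values[1], unstable = unstable),
            class = "eigen_system")
}

#' Orient and scale an eigenvector into a gradient
#'
#' Eigenvector sign is arbitrary; the convention here flips the vector when
#' its Spearman correlation with the anterior-posterior world coordinate is
#' negative (rostral = high), then min-max scales to `[0, 1]`.
#'
#' @param vec eigenvector values, one per voxel.
#' @param coords coordinate table rows matching `vec`.
#' @return numeric vector in `[0, 1]` with attribute `flipped`.
#' @export
orient_and_scale <- function(vec, coords) {
  if (length(vec) != nrow(coords)) stopf("vec must match the coordinate table rows")
  rng <- range(vec)
  if (diff(rng) < .Machine$double.eps) stopf("Degenerate (constant) gradient cannot be oriented")
  rho <- stats::cor(vec, coords$y, method = "spearman")
  flipped <- is.finite(rho) && rho < 0
  if (flipped) vec <- -vec
  vec <- (vec - min(vec)) / diff(range(vec))
  attr(vec, "flipped") <- flipped
  vec
}

# Impute gradient values for zero-variance voxels excluded upstream:
# mean over in-mask 6-neighbours (fallback: hemisphere mean).
impute_excluded <- function(values, coords, excluded) {
  for (v in excluded) {
    d <- abs(coords$i - coords$i[v]) + abs(coords$j - coords$j[v]) +
      abs(coords$k - coords$k[v])
    nb <- which(d == 1L)
    nb <- setdiff(nb, excluded)
    values[v] <- if (length(nb)) mean(values[nb])
    else mean(values[setdiff(which(coords$hemisphere == coords$hemisphere[v]), excluded)])
  }
  values
}

#' Dominant connectopic gradient of a similarity matrix
#'
#' Runs graph construction, Laplacian eigenmap, orientation and scaling
#' separately per hemisphere (left and right graphs are built from the
#' corresponding blocks of the joint similarity matrix) and assembles the
#' per-voxel gradient.
#'
#' @param S voxels x voxels similarity matrix (joint over hemispheres, rows
#'   in coordinate-table order).
#' @param coords the matching [coordinate_table()].
#' @param source `"subject"` or `"group"` provenance tag.
#' @param exclude integer indices of voxels excluded from the similarity
#'   computation (zero variance); their value is imputed from in-mask
#'   6-neighbours.
#' @return An object of class `gradient_map`: `values` in `[0, 1]`,
#'   `coords`, per-hemisphere `thresholds`, `eigenvalues`, `flipped` flags
#'   and `source`.
#' @export
roi_gradient <- function(S, coords, source = "subject", exclude = integer(0)) {
  values <- rep(NA_real_, nrow(coords))
  thresholds <- c(left = NA_real_, right = NA_real_)
  eigenvalues <- c(left = NA_real_, right = NA_real_)
  flips <- c(left = NA, right = NA)
  for (h in c("left", "right")) {
    sel <- which(coords$hemisphere == h)
    sel <- setdiff(sel, exclude)
    if (length(sel) < 3L) stopf("Hemisphere %s has fewer than 3 usable voxels", h)
    graph <- build_connected_graph(S[sel, sel, drop = FALSE])
    es <- laplacian_eigenmap(graph, 1L)
    g <- orient_and_scale(es$vectors[, 1], coords[sel, , drop = FALSE])
    values[sel] <- g
    thresholds[h] <- graph$threshold
    eigenvalues[h] <- es$values[1]
    flips[h] <- attr(g, "flipped")
  }
  if (length(exclude)) values <- impute_excluded(values, coords, exclude)
  structure(list(values = values, coords = coords, source = source,
                 thresholds = thresholds, eigenvalues = eigenvalues,
                 flipped = flips),
            class = "gradient_map")
}

#' @export
print.gradient_map <- function(x, ...) {
  cat(sprintf("<gradient_map> %s, %d voxels; thresholds L=%.3f R=%.3f; lambda1 L=%.4g R=%.4g\n",
              x$source, length(x$values), x$thresholds["left"], x$thresholds["right"],
              x$eigenvalues["left"], x$eigenvalues["right"]))
  invisible(x)
}

#' Group-level gradient from multiple subjects
#'
#' Averages the subjects' eta-squared similarity matrices element-wise and
#' computes one gradient from the average (avoiding per-subject eigenvector
#' sign and ordering alignment, which is unstable for small ROIs).
#'
#' @param S_list list of similarity matrices over the same voxel set.
#' @param coords the shared [coordinate_table()].
#' @param exclude voxel indices excluded upstream (imputed afterwards).
#' @return A `gradient_map` with `source = "group"`.
#' @export
group_gradient <- function(S_list, coords, exclude = integer(0)) {
  if (!length(S_list)) stopf("Empty similarity-matrix list")
  S <- Reduce(`+`, S_list) / length(S_list)
  roi_gradient(S, coords, source = "group", exclude = exclude)
}

#' Partition a gradient into rostral and caudal voxels
#'
#' With the rostral = high orientation convention, voxels above 0.5 are
#' labeled rostral, the rest caudal.
#'
#' @param gradient a `gradient_map` (or numeric vector of oriented values).
#' @return character vector of `"rostral"` / `"caudal"` labels.
#' @export
partition_rostral_caudal <- function(gradient) {
  v <- if (inherits(gradient, "gradient_map")) gradient$values else gradient
  ifelse(v > 0.5, "rostral", "caudal")
}

#' Rostral/caudal projection map of the target parcels
#'
#' For each parcel, finds the ROI voxel with maximal fingerprint
#' correlation and assigns the parcel that voxel's rostral/caudal label.
#' Given a list of subjects' fingerprints, the per-subject labels are
#' combined by majority (mode); ties in the maximal correlation are broken
#' by coordinate-table order and logged.
#'
#' @param fp fingerprint matrix, or a list of them (one per subject).
#' @param labels per-voxel labels from [partition_rostral_caudal()], or a
#'   list matching `fp`.
#' @return tibble with columns `parcel` and `label`.
#' @export
projection_map <- function(fp, labels) {
  if (is.list(fp) && !is.matrix(fp)) {
    stopifnot(is.list(labels), length(labels) == length(fp))
    per_subject <- purrr::map2(fp, labels, projection_map)
    votes <- dplyr::bind_rows(per_subject)
    return(votes |>
             dplyr::summarise(label = mode_label(.data$label), .by = "parcel"))
  }
  if (nrow(fp) != length(labels)) stopf("labels must cover all ROI voxels")
  parcel_label <- character(ncol(fp))
  for (p in seq_len(ncol(fp))) {
    col <- fp[, p]
    top <- which(col == max(col))
    if (length(top) > 1L) {
      message(sprintf("projection_map: tie for maximal correlation in parcel %d; using first voxel in coordinate order", p))
    }
    parcel_label[p] <- labels[top[1]]
  }
  tibble::tibble(parcel = colnames(fp) %||% as.character(seq_len(ncol(fp))),
                 label = parcel_label)
}

mode_label <- function(x) {
  tab <- sort(table(x), decreasing = TRUE)
  names(tab)[1]     # deterministic: alphabetical within equal counts
}

#' Write a gradient map as NIfTI plus JSON sidecar
#'
#' The scalar volume holds gradient values in `[0, 1]` with background 0;
#' the sidecar records per-hemisphere graph thresholds, eigenvalues and
#' orientation flips.
#'
#' @param x a `gradient_map`.
#' @param path output `.nii.gz` path; the sidecar replaces the extension
#'   with `.json`.
#' @param mask the [roi_mask()] defining the embedding grid.
#' @param ... unused.
#' @export
write_volume.gradient_map <- function(x, path, mask, ...) {
  vol <- array(0, dim = dim(mask$data))
  vol[which(mask$data)] <- x$values
  RNifti::writeNifti(nifti_from_array(vol, mask$affine), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(source = x$source,
                            thresholds = as.list(x$thresholds),
                            eigenvalues = as.list(x$eigenvalues),
                            flipped = as.list(x$flipped)),
                       sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
tidy.gradient_map <- function(x, ...) {
  out <- x$coords
  out$value <- x$values
  out$label <- partition_rostral_caudal(x$values)
  out
}
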