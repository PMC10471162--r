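#' BOLD volume container
#'
#' Wraps a 4D array of BOLD signal (x, y, z, time) with its voxel-to-world
#' affine and repetition time. Values must be finite and the time axis must
#' have at least 3 samples.
#'
#' @param data 4D numeric array.
#' @param affine 4x4 voxel-to-mm transform (0-based voxel indices).
#' @param tr_seconds repetition time in seconds (stored, not used
#'   numerically by the gradient computation).
#' @return An object of class `bold_volume`.
#' @export
bold_volume <- function(data, affine, tr_seconds = NA_real_) {
  if (length(dim(data)) != 4L) stopf("BOLD data must be a 4D array (x, y, z, time)")
  if (dim(data)[4] < 3L) stopf("BOLD time axis must have >= 3 timepoints, got %d", dim(data)[4])
  if (!all(is.finite(data))) stopf("BOLD data contains NaN/Inf values")
  affine <- validate_affine(affine)
  structure(list(data = data, affine = affine, tr_seconds = tr_seconds),
            class = "bold_volume")
}

#' ROI mask container
#'
#' A bilateral boolean mask with a left/right hemisphere assignment per
#' voxel. Both hemispheres must be present with at least 4 voxels each.
#'
#' @param hemisphere integer 3D array: 0 = background, 1 = left, 2 = right.
#' @param strict enforce the bilateral >= 4 voxels per hemisphere invariant
#'   (relax only for degenerate single-blob masks in smoothing utilities).
#' @inheritParams bold_volume
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(hemisphere, affine, strict = TRUE) {
  if (length(dim(hemisphere)) != 3L) stopf("mask must be a 3D array")
  hemisphere <- array(as.integer(hemisphere), dim = dim(hemisphere))
  n_left <- sum(hemisphere == 1L)
  n_right <- sum(hemisphere == 2L)
  if (strict && (n_left < 4L || n_right < 4L)) {
    stopf("ROI mask needs >= 4 voxels per hemisphere (left: %d, right: %d)", n_left, n_right)
  }
  affine <- validate_affine(affine)
  structure(list(data = hemisphere > 0L, hemisphere = hemisphere, affine = affine),
            class = "roi_mask")
}

#' Atlas label container
#'
#' @param data integer 3D array of parcel labels, 0 = background.
#' @param labels tibble with columns `label`, `name`, and optionally
#'   `target` (used by the phantom generator to tag rostral/caudal target
#'   parcels).
#' @inheritParams bold_volume
#' @return An object of class `atlas_labels`.
#' @export
atlas_labels <- function(data, labels, affine) {
  if (length(dim(data)) != 3L) stopf("atlas must be a 3D array")
  data <- array(as.integer(data), dim = dim(data))
  present <- sort(unique(data[data > 0L]))
  unknown <- setdiff(present, labels$label)
  if (length(unknown)) {
    stopf("Atlas contains labels absent from the label table: %s",
          paste(unknown, collapse = ", "))
  }
  affine <- validate_affine(affine)
  structure(list(data = data, labels = tibble::as_tibble(labels), affine = affine),
            class = "atlas_labels")
}

validate_affine <- function(affine) {
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stopf("affine must be a 4x4 matrix")
  storage.mode(affine) <- "double"
  affine
}

#' Coordinate table of a mask
#'
#' One row per in-mask voxel in ascending flat-index order (x fastest,
#' which is R's native column-major array order): 0-based voxel indices,
#' world coordinates in mm (`world = affine %*% c(i, j, k, 1)`), and the
#' hemisphere assignment.
#'
#' @param mask an [roi_mask()].
#' @return A tibble with columns `voxel`, `i`, `j`, `k`, `x`, `y`, `z`,
#'   `hemisphere`.
#' @export
coordinate_table <- function(mask) {
  stopifnot(inherits(mask, "roi_mask"))
  idx <- which(mask$data)                      # ascending flat index
  dims <- dim(mask$data)
  ijk <- arrayInd(idx, dims) - 1L              # 0-based
  xyz <- apply_affine(mask$affine, ijk)
  tibble::tibble(
    voxel = seq_along(idx),
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    hemisphere = c("left", "right")[mask$hemisphere[idx]]
  )
}

# ---- NIfTI input/output ----------------------------------------------------

nifti_from_array <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- vox
  RNifti::qform(img) <- structure(affine, code = 2L)
  RNifti::sform(img) <- structure(affine, code = 2L)
  img
}

nifti_affine <- function(img) {
  aff <- RNifti::xform(img, useQuaternionFirst = FALSE)
  matrix(as.numeric(aff), 4L, 4L)
}

#' Read and write volumes as NIfTI-1
#'
#' `load_bold()` reads a 4D volume; `load_mask()` a hemisphere-coded ROI
#' mask (values 1 = left, 2 = right; plain binary masks are split by the
#' sign of the world x coordinate, left = x < 0); `load_atlas()` an integer
#' label volume checked against a label table. Grids/affines of inputs used
#' together are validated downstream; mismatches are hard errors, never a
#' silent resample.
#'
#' @param path file path (.nii or .nii.gz).
#' @param tr_seconds repetition time to record on the loaded volume.
#' @return The corresponding container object.
#' @export
load_bold <- function(path, tr_seconds = NA_real_) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  bold_volume(arr, nifti_affine(img), tr_seconds)
}

#' @rdname load_bold
#' @export
load_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- round(as.array(img))
  affine <- nifti_affine(img)
  if (!any(arr > 1)) {
    # plain binary mask: assign hemisphere by world x sign
    idx <- which(arr > 0)
    ijk <- arrayInd(idx, dim(arr)) - 1L
    xw <- apply_affine(affine, ijk)[, 1]
    hemi <- array(0L, dim = dim(arr))
    hemi[idx] <- ifelse(xw < 0, 1L, 2L)
    arr <- hemi
  }
  roi_mask(arr, affine)
}

#' @rdname load_bold
#' @param labels label table (tibble with `label`, `name`) for `load_atlas()`.
#' @export
load_atlas <- function(path, labels) {
  img <- RNifti::readNifti(path)
  atlas_labels(round(as.array(img)), labels, nifti_affine(img))
}

#' Write a container to a NIfTI-1 file
#'
#' @param x a `bold_volume`, `roi_mask`, `atlas_labels` or `gradient_map`.
#' @param path output path (.nii.gz recommended).
#' @param ... passed on to methods.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, ...) UseMethod("write_volume")

#' @export
write_volume.bold_volume <- function(x, path, ...) {
  RNifti::writeNifti(nifti_from_array(x$data, x$affine), path)
  invisible(path)
}

#' @export
write_volume.roi_mask <- function(x, path, ...) {
  RNifti::writeNifti(nifti_from_array(x$hemisphere, x$affine), path)
  invisible(path)
}

#' @export
write_volume.atlas_labels <- function(x, path, ...) {
  RNifti::writeNifti(nifti_from_array(x$data, x$affine), path)
  invisible(path)
}

# ---- Time-series extraction ------------------------------------------------

# voxels x time matrix view of the 4D array, in flat-index order
vox_by_time <- function(bold) {
  d <- dim(bold$data)
  matrix(bold$data, prod(d[1:3]), d[4])
}

#' Extract ROI voxel time series
#'
#' Returns the in-mask voxel-by-time matrix in [coordinate_table()] row
#' order, together with that table. Voxels whose series have zero variance
#' are flagged in the `zero_variance` attribute of the matrix (they are
#' excluded from correlation computations downstream and their gradient
#' value imputed from in-mask neighbours).
#'
#' @param bold a [bold_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @return list with elements `ts` (voxels x time matrix) and `coords`.
#' @export
extract_roi_timeseries <- function(bold, mask) {
  check_compatible(dim(bold$data), bold$affine, dim(mask$data), mask$affine,
                   "BOLD volume and ROI mask")
  coords <- coordinate_table(mask)
  ts <- vox_by_time(bold)[which(mask$data), , drop = FALSE]
  zv <- which(matrixStats_rowVars(ts) < .Machine$double.eps)
  attr(ts, "zero_variance") <- zv
  if (length(zv)) {
    message(sprintf("%d ROI voxel(s) have zero-variance time series; flagged for imputation", length(zv)))
  }
  list(ts = ts, coords = coords)
}

matrixStats_rowVars <- function(m) {
  # row variances without a matrixStats dependency
  n <- ncol(m)
  mu <- rowMeans(m)
  (rowSums(m^2) - n * mu^2) / (n - 1)
}

#' Extract mean parcel time series
#'
#' Averages the time series of all voxels sharing each atlas label. Rows
#' are ordered by ascending label; parcels with no voxels in the volume are
#' dropped with a warning.
#'
#' @param bold a [bold_volume()].
#' @param atlas an [atlas_labels()] on the same grid.
#' @return parcels x time matrix with labels as row names.
#' @export
extract_parcel_timeseries <- function(bold, atlas) {
  check_compatible(dim(bold$data), bold$affine, dim(atlas$data), atlas$affine,
                   "BOLD volume and atlas")
  lab <- as.integer(atlas$data)
  sel <- lab > 0L
  if (!any(sel)) stopf("All atlas parcels are empty")
  vmat <- vox_by_time(bold)
  sums <- rowsum(vmat[sel, , drop = FALSE], lab[sel])   # sorted by label
  counts <- as.vector(table(lab[sel]))
  out <- sums / counts
  missing <- setdiff(atlas$labels$label, as.integer(rownames(out)))
  if (length(missing)) {
    warnf("Dropping empty parcel(s): %s", paste(missing, collapse = ", "))
  }
  out
}

# ---- Nuisance regression and smoothing -------------------------------------

#' Remove nuisance signals by voxel-wise least squares
#'
#' Each voxel's series is replaced by the residuals of an ordinary
#' least-squares fit on an intercept plus the given regressors. With no
#' regressors this demeans every voxel.
#'
#' @param bold a [bold_volume()].
#' @param regressors time x k numeric matrix (or NULL for intercept only).
#' @return A new `bold_volume` of residuals.
#' @export
regress_nuisance <- function(bold, regressors = NULL) {
  nt <- dim(bold$data)[4]
  X <- cbind(intercept = rep(1, nt), regressors)
  if (ncol(X) >= nt) stopf("Need fewer regressors (%d) than timepoints (%d)", ncol(X) - 1L, nt)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stopf("Nuisance regressor matrix is rank-deficient")
  Q <- qr.Q(qrX)
  vmat <- vox_by_time(bold)
  res <- vmat - (vmat %*% Q) %*% t(Q)
  out <- bold
  out$data <- array(res, dim = dim(bold$data))
  out
}

# Mask-renormalized Gaussian weight matrix between in-mask voxels.
# fwhm in mm; distances from world coordinates; weights renormalized so
# each row sums to 1 (no signal leaks across the mask boundary, constants
# are preserved exactly).
mask_kernel <- function(coords, fwhm_mm) {
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  d2 <- as.matrix(stats::dist(xyz))^2
  W <- exp(-d2 / (2 * sigma^2))
  W / rowSums(W)
}

smooth_ts <- function(ts, coords, fwhm_mm) {
  mask_kernel(coords, fwhm_mm) %*% ts
}

#' Gaussian smoothing restricted to a mask
#'
#' Smooths each timepoint with an isotropic Gaussian kernel of the given
#' FWHM using only in-mask voxels, renormalizing kernel weights at the mask
#' boundary so no signal leaks in from (or out to) surrounding tissue.
#' Out-of-mask voxels are returned unchanged.
#'
#' @param bold a [bold_volume()].
#' @param mask an [roi_mask()] on the same grid.
#' @param fwhm_mm kernel full width at half maximum in mm
#'   (sigma = fwhm / (2 sqrt(2 log 2)) per axis).
#' @return A new `bold_volume`.
#' @export
smooth_within_mask <- function(bold, mask, fwhm_mm) {
  if (!is.numeric(fwhm_mm) || fwhm_mm <= 0) stopf("fwhm_mm must be > 0")
  if (!any(mask$data)) stopf("ROI mask is empty")
  check_compatible(dim(bold$data), bold$affine, dim(mask$data), mask$affine,
                   "BOLD volume and ROI mask")
  coords <- coordinate_table(mask)
  idx <- which(mask$data)
  d <- dim(bold$data)
  vmat <- vox_by_time(bold)
  vmat[idx, ] <- smooth_ts(vmat[idx, , drop = FALSE], coords, fwhm_mm)
  out <- bold
  out$data <- array(vmat, dim = d)
  out
}
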