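test_that("NIfTI round trip preserves data and affine", {
  cfg <- phantom_config(n_timepoints = 5L)
  sub <- simulate_subject(cfg, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(sub$bold, tmp)
  back <- load_bold(tmp)
  expect_equal(back$data, unclass(sub$bold$data), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_lt(max(abs(back$affine - sub$bold$affine)), 1e-6)

  mtmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(sub$mask, mtmp)
  mask2 <- load_mask(mtmp)
  expect_identical(mask2$hemisphere, sub$mask$hemisphere)
})

test_that("grid or affine mismatches are hard errors", {
  cfg <- phantom_config(n_timepoints = 5L)
  sub <- simulate_subject(cfg, seed = 1)
  small <- roi_mask(array(rep(c(0L, 1L, 2L), c(6, 1, 1)), dim = c(2, 2, 2)),
                    diag(4), strict = FALSE)
  expect_error(extract_roi_timeseries(sub$bold, small), "Incompatible")
  shifted <- sub$mask
  shifted$affine[1, 4] <- shifted$affine[1, 4] + 1
  expect_error(extract_roi_timeseries(sub$bold, shifted), "affines differ")
})

test_that("atlas loading rejects labels missing from the table", {
  cfg <- phantom_config()
  atlas <- make_phantom_atlas(cfg)
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(atlas, tmp)
  expect_error(load_atlas(tmp, atlas$labels[-1, ]), "absent from the label table")
  back <- load_atlas(tmp, atlas$labels)
  expect_identical(back$data, atlas$data)
})

test_that("nuisance regression matches the normal-equations solution", {
  set.seed(42)
  cfg <- phantom_config(n_timepoints = 30L)
  sub <- simulate_subject(cfg, seed = 2)
  reg <- matrix(rnorm(30 * 2), 30, 2)
  out <- regress_nuisance(sub$bold, reg)

  X <- cbind(1, reg)
  beta_hat <- solve(t(X) %*% X) %*% t(X)
  idx <- which(sub$mask$data)
  vin <- matrix(sub$bold$data, prod(dim(sub$mask$data)), 30)[idx, ]
  vout <- matrix(out$data, prod(dim(sub$mask$data)), 30)[idx, ]
  expected <- vin - t(X %*% (beta_hat %*% t(vin)))
  expect_lt(max(abs(vout - expected)), 1e-8)

  # intercept-only call demeans; a series equal to a regressor is zeroed
  demeaned <- regress_nuisance(sub$bold, NULL)
  v1 <- matrix(demeaned$data, prod(dim(sub$mask$data)), 30)[idx[1], ]
  expect_equal(v1, vin[1, ] - mean(vin[1, ]), tolerance = 1e-10)

  bold2 <- sub$bold
  m <- matrix(bold2$data, prod(dim(sub$mask$data)), 30)
  m[idx[1], ] <- reg[, 1]
  bold2$data <- array(m, dim = dim(bold2$data))
  res2 <- regress_nuisance(bold2, reg)
  expect_lt(max(abs(matrix(res2$data, prod(dim(sub$mask$data)), 30)[idx[1], ])), 1e-10)

  expect_error(regress_nuisance(sub$bold, cbind(reg[, 1], reg[, 1])),
               "rank-deficient")
})

test_that("mask-constrained smoothing preserves constants and never leaks", {
  cfg <- phantom_config(n_timepoints = 4L)
  sub <- simulate_subject(cfg, seed = 5)
  bold <- sub$bold
  nvox <- prod(dim(sub$mask$data))
  m <- matrix(bold$data, nvox, 4)
  idx <- which(sub$mask$data)
  m[idx, ] <- 3.25
  bold$data <- array(m, dim = dim(bold$data))
  sm <- smooth_within_mask(bold, sub$mask, fwhm_mm = 3)
  msm <- matrix(sm$data, nvox, 4)
  expect_equal(msm[idx, ], m[idx, ], tolerance = 1e-12)
  # out-of-mask voxels bit-identical
  expect_identical(msm[-idx, ], m[-idx, ])
})

test_that("single-voxel masks and the 1D three-voxel kernel behave as derived", {
  # single in-mask voxel: smoothing is the identity
  hemi <- array(0L, dim = c(3, 3, 3)); hemi[2, 2, 2] <- 1L
  mask1 <- roi_mask(hemi, diag(c(2, 2, 2, 1)), strict = FALSE)
  arr <- array(rnorm(27 * 3), dim = c(3, 3, 3, 3))
  sm <- smooth_within_mask(bold_volume(arr, diag(c(2, 2, 2, 1))), mask1, 3)
  expect_equal(sm$data, arr, tolerance = 1e-12)

  # 1D mask of three voxels, unit impulse at the centre:
  # centre value = w0 / (w0 + 2 w1) by kernel renormalization
  hemi3 <- array(0L, dim = c(5, 1, 1)); hemi3[2:4, 1, 1] <- 1L
  mask3 <- roi_mask(hemi3, diag(c(2, 2, 2, 1)), strict = FALSE)
  arr3 <- array(0, dim = c(5, 1, 1, 3)); arr3[3, 1, 1, 1] <- 1
  fwhm <- 3
  sm3 <- smooth_within_mask(bold_volume(arr3, diag(c(2, 2, 2, 1)), tr_seconds = 1),
                            mask3, fwhm)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w1 <- exp(-2^2 / (2 * sigma^2))
  expect_equal(sm3$data[3, 1, 1, 1], 1 / (1 + 2 * w1), tolerance = 1e-12)
  expect_equal(sm3$data[2, 1, 1, 1], w1 / (1 + w1 + exp(-4^2 / (2 * sigma^2))),
               tolerance = 1e-12)
})

test_that("parcel extraction averages voxels and matches a brute-force regroup", {
  cfg <- phantom_config(n_timepoints = 6L)
  sub <- simulate_subject(cfg, seed = 3)
  pts <- extract_parcel_timeseries(sub$bold, sub$atlas)
  lab <- as.integer(sub$atlas$data)
  vmat <- matrix(sub$bold$data, prod(dim(sub$atlas$data)), 6)
  for (p in sort(unique(lab[lab > 0]))) {
    expect_equal(pts[as.character(p), ], colMeans(vmat[lab == p, , drop = FALSE]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # tiny hand case: two voxels (1,2,3) and (3,4,5) average to (2,3,4)
  vol <- array(0, dim = c(2, 1, 1, 3))
  vol[1, 1, 1, ] <- c(1, 2, 3); vol[2, 1, 1, ] <- c(3, 4, 5)
  at <- atlas_labels(array(1L, dim = c(2, 1, 1)),
                     tibble::tibble(label = 1L, name = "p"), diag(4))
  expect_equal(as.vector(extract_parcel_timeseries(bold_volume(vol, diag(4)), at)),
               c(2, 3, 4))
})

test_that("ROI extraction follows coordinate-table order and affine math", {
  cfg <- phantom_config(n_timepoints = 5L)
  sub <- simulate_subject(cfg, seed = 4)
  roi <- extract_roi_timeseries(sub$bold, sub$mask)
  expect_equal(nrow(roi$ts), 96L)
  expect_equal(nrow(roi$coords), 96L)
  # world = affine %*% (i, j, k, 1)
  i <- 17
  expected <- sub$bold$affine %*% c(roi$coords$i[i], roi$coords$j[i], roi$coords$k[i], 1)
  expect_equal(c(roi$coords$x[i], roi$coords$y[i], roi$coords$z[i]),
               expected[1:3], tolerance = 1e-12)
  # row order is ascending flat index (x fastest)
  idx <- which(sub$mask$data)
  ijk <- arrayInd(idx, dim(sub$mask$data)) - 1L
  expect_equal(cbind(roi$coords$i, roi$coords$j, roi$coords$k), unname(ijk))
})
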