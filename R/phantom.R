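#' Phantom configuration
#'
#' Describes the synthetic imaging phantom: a bilateral ROI of two
#' elongated blobs (the rostro-caudal long axis runs along the
#' anterior-posterior world axis), a block parcellation standing in for a
#' cortical + subcortical atlas, and BOLD-like time series in which each
#' ROI voxel mixes a shared "rostral" and a shared "caudal" latent signal
#' according to a planted monotone field.
#'
#' @param grid_shape 3 positive integers, voxel grid size.
#' @param voxel_size_mm isotropic voxel edge in mm.
#' @param n_timepoints length of the simulated time series (>= 3).
#' @param n_cortical_parcels,n_subcortical_parcels parcel counts (>= 2 each).
#' @param rostral_extent fraction (0-1) of the ROI long axis expressing
#'   rostral-like connectivity; the planted logistic field has its midpoint
#'   here.
#' @param sharpness logistic steepness of the planted field; larger values
#'   give a more clustered (two-block) gradient.
#' @param noise_sd time-series noise SD relative to the unit-variance
#'   latent signals.
#' @param latent_cor correlation between the rostral and caudal latent
#'   signals (distinct but not orthogonal profiles).
#' @param seed integer seed for all randomness derived from this config.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(20L, 20L, 30L),
                           voxel_size_mm = 2,
                           n_timepoints = 150L,
                           n_cortical_parcels = 12L,
                           n_subcortical_parcels = 6L,
                           rostral_extent = 0.55,
                           sharpness = 8,
                           noise_sd = 0.1,
                           latent_cor = 0.3,
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) stopf("grid_shape must be 3 positive integers")
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  if (n_timepoints < 3L) stopf("n_timepoints must be >= 3")
  if (n_cortical_parcels < 2L || n_subcortical_parcels < 2L) stopf("parcel counts must be >= 2")
  if (rostral_extent < 0 || rostral_extent > 1) stopf("rostral_extent must lie in [0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be nonnegative")
  if (abs(latent_cor) >= 1) stopf("latent_cor must lie in (-1, 1)")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints),
                 n_cortical_parcels = as.integer(n_cortical_parcels),
                 n_subcortical_parcels = as.integer(n_subcortical_parcels),
                 rostral_extent = rostral_extent, sharpness = sharpness,
                 noise_sd = noise_sd, latent_cor = latent_cor,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Blob shape per hemisphere: a 2 x 2 (medio-lateral x dorso-ventral)
# cross-section swept along 12 anterior-posterior sections, 48 voxels
# each. The sweep is curved: every 3 sections the cross-section shifts one
# voxel medially and one dorsally (the nucleus is not a straight block),
# which also gives every coordinate axis enough distinct levels to
# identify all nine pure-power trend-surface terms.
phantom_blob_dims <- c(2L, 12L, 2L)
phantom_blob_shift <- function(section) (section - 1L) %/% 3L   # 0..3 over 12 sections

phantom_geometry <- function(config) {
  g <- config$grid_shape
  b <- phantom_blob_dims
  max_shift <- phantom_blob_shift(b[2])
  span_x <- b[1] + max_shift
  need <- c(2L * span_x + 4L, b[2] + 4L, b[3] + max_shift + 4L)
  if (any(g < need)) {
    stopf("Grid %s too small for two curved %s hemispheric blobs; minimum grid is %s",
          paste(g, collapse = "x"), paste(b, collapse = "x"), paste(need, collapse = "x"))
  }
  y0 <- (g[2] - b[2]) %/% 2L
  z0 <- (g[3] - b[3] - max_shift) %/% 2L
  quarter <- g[1] %/% 5L
  list(left_x0 = quarter,                                 # 0-based lateral edge
       right_x0 = g[1] - quarter - b[1],
       y0 = y0, z0 = z0, b = b, max_shift = max_shift)
}

phantom_affine <- function(config) {
  g <- config$grid_shape
  v <- config$voxel_size_mm
  aff <- diag(c(v, v, v, 1))
  aff[1:3, 4] <- -v * (g - 1) / 2   # RAS, origin at grid centre
  aff
}

#' Build the phantom bilateral ROI mask
#'
#' Two disjoint elongated blobs (one per hemisphere), elongated along the
#' anterior-posterior axis, with a diagonal RAS affine centred on the grid.
#' Deterministic given the configuration.
#'
#' @param config a [phantom_config()].
#' @return An [roi_mask()].
#' @export
make_phantom_roi <- function(config) {
  geo <- phantom_geometry(config)
  hemi <- array(0L, dim = config$grid_shape)
  b <- geo$b
  for (section in seq_len(b[2])) {
    s <- phantom_blob_shift(section)
    y <- geo$y0 + section                                  # 1-based
    z <- geo$z0 + s + seq_len(b[3])
    hemi[geo$left_x0 + s + seq_len(b[1]), y, z] <- 1L      # left shifts medially (+x)
    hemi[geo$right_x0 - s + seq_len(b[1]), y, z] <- 2L     # right shifts medially (-x)
  }
  roi_mask(hemi, phantom_affine(config))
}

#' Build the phantom parcellation
#'
#' Places `n_cortical_parcels + n_subcortical_parcels` contiguous 3x3x3
#' blocks on a lattice, skipping any position overlapping (or adjacent to)
#' the ROI. Parcels are alternately tagged `rostral` / `caudal` targets:
#' rostral-target parcels receive the rostral latent signal, caudal-target
#' parcels the caudal one.
#'
#' @param config a [phantom_config()].
#' @return An [atlas_labels()] whose label table has columns `label`,
#'   `name`, `target`.
#' @export
make_phantom_atlas <- function(config) {
  mask <- make_phantom_roi(config)
  g <- config$grid_shape
  n_parcels <- config$n_cortical_parcels + config$n_subcortical_parcels
  # candidate block origins (0-based) on a stride-4 lattice
  ox <- seq(1L, g[1] - 4L, by = 4L)
  oy <- seq(1L, g[2] - 4L, by = 4L)
  oz <- seq(1L, g[3] - 4L, by = 4L)
  cand <- expand.grid(x = ox, y = oy, z = oz, KEEP.OUT.ATTRS = FALSE)
  ijk <- arrayInd(which(mask$data), g) - 1L
  roi_x <- range(ijk[, 1]); roi_y <- range(ijk[, 2]); roi_z <- range(ijk[, 3])
  clear <- function(o, r) (o + 2L) < (r[1] - 1L) | o > (r[2] + 1L)
  ok <- clear(cand$x, roi_x) | clear(cand$y, roi_y) | clear(cand$z, roi_z)
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) < n_parcels) {
    stopf("Grid %s cannot hold %d non-overlapping 3x3x3 parcels clear of the ROI (room for %d)",
          paste(g, collapse = "x"), n_parcels, nrow(cand))
  }
  cand <- cand[order(cand$z, cand$y, cand$x), , drop = FALSE][seq_len(n_parcels), ]
  vol <- array(0L, dim = g)
  for (p in seq_len(n_parcels)) {
    vol[cand$x[p] + 1:3, cand$y[p] + 1:3, cand$z[p] + 1:3] <- p
  }
  kind <- rep(c("cortical", "subcortical"),
              c(config$n_cortical_parcels, config$n_subcortical_parcels))
  labels <- tibble::tibble(
    label = seq_len(n_parcels),
    name = sprintf("%s_%02d", kind, seq_len(n_parcels)),
    target = ifelse(seq_len(n_parcels) %% 2L == 1L, "rostral", "caudal")
  )
  atlas_labels(vol, labels, phantom_affine(config))
}

# Rostro-caudal coordinate t in [0, 1] per ROI voxel: 0 at the rostral
# (anterior, largest y) tip, 1 at the caudal tip. The designated long axis
# is slightly oblique - dominated by the anterior-posterior direction with
# small dorso-ventral and (mirror-symmetric) lateral components - so every
# ROI voxel has a distinct planted coordinate while orientation by the
# anterior-posterior world coordinate remains unambiguous.
rostrocaudal_coordinate <- function(coords) {
  rng01 <- function(v) {
    r <- diff(range(v))
    if (r < .Machine$double.eps) rep(0, length(v)) else (max(v) - v) / r
  }
  y_r <- rng01(coords$y)
  z_r <- rng01(coords$z)
  # lateral position within each cross-section, measured from the section's
  # medial voxel (mirror-symmetric: medial = largest x on the left,
  # smallest x on the right)
  section <- interaction(coords$hemisphere, coords$j, drop = TRUE)
  lat <- ifelse(coords$hemisphere == "left",
                stats::ave(coords$x, section, FUN = max) - coords$x,
                coords$x - stats::ave(coords$x, section, FUN = min))
  lat_r <- if (diff(range(lat)) < .Machine$double.eps) rep(0, length(lat)) else lat / max(lat)
  (y_r + 0.12 * z_r + 0.05 * lat_r) / 1.17
}

# Planted caudal-ness field: logistic in t with midpoint rostral_extent.
planted_field <- function(tcoord, rostral_extent, sharpness) {
  stats::plogis(sharpness * (tcoord - rostral_extent))
}

#' Simulate one subject's phantom BOLD data
#'
#' Every ROI voxel's series is `(1 - g) * s_rostral + g * s_caudal + noise`
#' where `g` is the planted monotone field along the rostro-caudal axis and
#' the two unit-variance latent signals (correlated by `latent_cor`) are
#' also injected into the rostral-/caudal-target parcels. The returned
#' truth records the planted field and its trend-surface summary.
#'
#' @param config a [phantom_config()].
#' @param truth_params optional list overriding `rostral_extent` and
#'   `sharpness` from the config (used by [simulate_cohort()]).
#' @param format `"volume"` to return a full 4D [bold_volume()] (background
#'   voxels are zero), `"timeseries"` to return only the ROI and parcel
#'   time-series matrices (identical values, no 4D packing).
#' @param seed seed for this subject (defaults to `config$seed`).
#' @param scaffold optional precomputed static phantom pieces (internal
#'   cache used by [simulate_cohort()]).
#' @return list with elements `bold` (or `roi_ts` + `parcel_ts`), `mask`,
#'   `atlas`, `coords` and `truth`.
#' @export
simulate_subject <- function(config, truth_params = NULL,
                             format = c("volume", "timeseries"),
                             seed = config$seed, scaffold = NULL) {
  format <- match.arg(format)
  if (config$noise_sd < 0) stopf("noise_sd must be nonnegative")
  scaffold <- scaffold %||% phantom_scaffold(config)
  mask <- scaffold$mask
  atlas <- scaffold$atlas
  coords <- scaffold$coords
  rostral_extent <- truth_params$rostral_extent %||% config$rostral_extent
  sharpness <- truth_params$sharpness %||% config$sharpness
  rostral_extent <- min(1, max(0, rostral_extent))

  gfield <- planted_field(scaffold$tcoord, rostral_extent, sharpness)
  nt <- config$n_timepoints
  nvox <- nrow(coords)
  parcel_vox <- scaffold$parcel_vox
  parcel_of <- scaffold$parcel_of

  draws <- with_seed(seed, {
    list(z0 = stats::rnorm(nt), z1 = stats::rnorm(nt), z2 = stats::rnorm(nt),
         roi_noise = matrix(stats::rnorm(nvox * nt), nvox, nt),
         parcel_noise = matrix(stats::rnorm(length(parcel_vox) * nt),
                               length(parcel_vox), nt))
  })
  s_global <- draws$z0
  s_rostral <- draws$z1
  s_caudal <- config$latent_cor * draws$z1 +
    sqrt(1 - config$latent_cor^2) * draws$z2

  # voxels carry a shared global component (weight 0.5) on top of the
  # rostral/caudal mixture; parcels carry the same global component with a
  # parcel-specific loading so connectivity fingerprints have diverse
  # baseline levels (as real parcel profiles do) rather than collapsing to
  # two values, which would make the eta-squared kernel degenerate for
  # mid-gradient voxels.
  n_parcels <- nrow(atlas$labels)
  q_j <- 0.2 + 0.6 * (seq_len(n_parcels) - 1) / (n_parcels - 1)
  latents <- rbind(s_global, s_rostral, s_caudal)
  roi_mix <- cbind(0.5, 1 - gfield, gfield)
  roi_ts <- roi_mix %*% latents
  if (config$noise_sd > 0) roi_ts <- roi_ts + config$noise_sd * draws$roi_noise
  is_caudal <- atlas$labels$target[parcel_of] == "caudal"
  parcel_mix <- cbind(q_j[parcel_of], 1 - is_caudal, as.numeric(is_caudal))
  parcel_vox_ts <- parcel_mix %*% latents
  if (config$noise_sd > 0) {
    parcel_vox_ts <- parcel_vox_ts + config$noise_sd * draws$parcel_noise
  }

  planted_tsm <- planted_tsm_fit(1 - gfield, coords, scaffold$basis)
  truth <- list(rostral_extent = rostral_extent, sharpness = sharpness,
                planted_field = gfield, planted_tsm = planted_tsm)

  if (format == "timeseries") {
    parcel_ts <- rowsum(parcel_vox_ts, parcel_of) /
      as.vector(table(parcel_of))
    return(list(roi_ts = roi_ts, parcel_ts = parcel_ts, mask = mask,
                atlas = atlas, coords = coords, truth = truth))
  }
  vol <- array(0, dim = c(config$grid_shape, nt))
  vmat <- matrix(vol, prod(config$grid_shape), nt)
  vmat[which(mask$data), ] <- roi_ts
  vmat[parcel_vox, ] <- parcel_vox_ts
  bold <- bold_volume(array(vmat, dim = c(config$grid_shape, nt)),
                      phantom_affine(config))
  list(bold = bold, mask = mask, atlas = atlas, coords = coords, truth = truth)
}

# Static phantom pieces shared by every simulated subject of one config.
phantom_scaffold <- function(config) {
  mask <- make_phantom_roi(config)
  atlas <- make_phantom_atlas(config)
  coords <- coordinate_table(mask)
  lab <- as.integer(atlas$data)
  parcel_vox <- which(lab > 0L)
  list(mask = mask, atlas = atlas, coords = coords,
       tcoord = rostrocaudal_coordinate(coords),
       parcel_vox = parcel_vox, parcel_of = lab[parcel_vox],
       basis = lapply(stats::setNames(c("left", "right"), c("left", "right")),
                      function(h) tsm_basis(coords, h)))
}

# Ordinary least-squares trend-surface summary of the planted rostrality
# field (independent of the package's Bayesian fit; generator-internal).
planted_tsm_fit <- function(values, coords, basis = NULL) {
  lapply(stats::setNames(c("left", "right"), c("left", "right")), function(h) {
    B <- if (is.null(basis)) tsm_basis(coords, h) else basis[[h]]
    fit <- stats::lm.fit(cbind(1, B), values[attr(B, "rows")])
    stats::setNames(fit$coefficients[-1], colnames(B))
  })
}

#' Default cohort effect configuration
#'
#' Effect sizes and score moments used by [simulate_cohort()]. Ages shift
#' the planted rostral extent (`age_effect`, per year, applied around the
#' cohort mean age) and the logistic sharpness (`sharpness_age_effect`).
#' `em_recognition` is coupled (correlation `em_coupling`) to the planted
#' linear anterior-posterior trend-surface coefficient, `er_reactivity` to
#' the planted rostral extent; all other scores are pure noise with moments
#' matching the cohort description table. Subjects in the high-HADS group
#' (anxiety/depression screening score above 7) have their rostral extent
#' shifted by `hads_effect`.
#'
#' @param age_effect per-year change in rostral extent.
#' @param rostral_noise_sd between-subject SD of rostral extent.
#' @param base_sharpness,sharpness_age_effect,sharpness_noise_sd planted
#'   clusterability and its age coupling.
#' @param em_coupling,er_coupling correlations of the two coupled scores
#'   with their planted spatial parameters.
#' @param hads_effect additive shift of rostral extent in the high-HADS
#'   group.
#' @return list of class `cohort_effects`.
#' @export
cohort_effects <- function(age_effect = -0.005,
                           rostral_noise_sd = 0.04,
                           base_sharpness = 8,
                           sharpness_age_effect = 0.06,
                           sharpness_noise_sd = 0.6,
                           em_coupling = 0.8,
                           er_coupling = 0.8,
                           hads_effect = -0.08) {
  eff <- list(age_effect = age_effect, rostral_noise_sd = rostral_noise_sd,
              base_sharpness = base_sharpness,
              sharpness_age_effect = sharpness_age_effect,
              sharpness_noise_sd = sharpness_noise_sd,
              em_coupling = em_coupling, er_coupling = er_coupling,
              hads_effect = hads_effect)
  if (!all(vapply(eff, is.finite, logical(1)))) stopf("effect sizes must be finite")
  structure(eff, class = "cohort_effects")
}

score_names <- c("em_recollection", "em_recognition", "em_priming",
                 "er_reactivity", "er_reappraisal", "hotel", "psqi", "hads")

#' Simulate a phantom cohort with planted age and behavioral effects
#'
#' Draws ages uniformly over `age_range`, plants per-subject rostral extent
#' `base + age_effect * (age - mean age) + noise` (clipped to `[0, 1]`, plus
#' the HADS-group shift), simulates each subject's phantom BOLD data, and
#' generates behavioral scores as noisy functions of the planted spatial
#' parameters. By default each subject is reduced immediately to its
#' connectivity fingerprints and eta-squared similarity matrix (after
#' within-mask smoothing), which is what all group analyses consume.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range numeric length-2, min < max.
#' @param effects a [cohort_effects()].
#' @param config a [phantom_config()]; `config$rostral_extent` is the
#'   cohort base value.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param fwhm_mm within-mask smoothing applied before fingerprints.
#' @param keep `"similarity"` (default) or `"timeseries"` to also retain
#'   per-subject ROI/parcel series.
#' @return An object of class `lc_cohort`: `covariates` (tibble with id,
#'   age, sex, education and all score columns), `sims` (per-subject
#'   similarity matrices), `fingerprints`, `coords`, `truth`, `effects`,
#'   `config`, `seed`.
#' @export
simulate_cohort <- function(n_subjects, age_range = c(18, 88),
                            effects = cohort_effects(),
                            config = phantom_config(),
                            seed = 1L, fwhm_mm = 3,
                            keep = c("similarity", "timeseries")) {
  keep <- match.arg(keep)
  if (n_subjects < 2L) stopf("n_subjects must be >= 2")
  if (age_range[1] >= age_range[2]) stopf("Degenerate age_range: min must be < max")
  mask <- make_phantom_roi(config)
  coords <- coordinate_table(mask)

  cohort <- with_seed(seed, {
    age <- stats::runif(n_subjects, age_range[1], age_range[2])
    sex <- stats::rbinom(n_subjects, 1L, 0.5)
    education <- pmax(0, stats::rnorm(n_subjects, 14.56, 4.02))
    hads <- pmin(20, round(stats::rgamma(n_subjects, shape = 2.2, scale = 2.5)))
    psqi <- pmin(22, round(stats::rgamma(n_subjects, shape = 2.0, scale = 2.4)))
    age_c <- age - mean(age)
    rostral_extent <- config$rostral_extent + effects$age_effect * age_c +
      stats::rnorm(n_subjects, 0, effects$rostral_noise_sd) +
      ifelse(hads > 7, effects$hads_effect, 0)
    rostral_extent <- pmin(1, pmax(0, rostral_extent))
    sharpness <- pmax(1, effects$base_sharpness +
                        effects$sharpness_age_effect * age_c +
                        stats::rnorm(n_subjects, 0, effects$sharpness_noise_sd))
    subject_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    score_noise <- matrix(stats::rnorm(n_subjects * 8L), n_subjects, 8L)
    list(age = age, sex = sex, education = education, hads = hads, psqi = psqi,
         rostral_extent = rostral_extent, sharpness = sharpness,
         subject_seeds = subject_seeds, score_noise = score_noise)
  })

  scaffold <- phantom_scaffold(config)
  kern <- mask_kernel(coords, fwhm_mm)
  sims <- vector("list", n_subjects)
  fps <- vector("list", n_subjects)
  truth_subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sub <- simulate_subject(config,
                            truth_params = list(rostral_extent = cohort$rostral_extent[s],
                                                sharpness = cohort$sharpness[s]),
                            format = "timeseries", seed = cohort$subject_seeds[s],
                            scaffold = scaffold)
    roi_ts <- kern %*% sub$roi_ts
    fp <- fingerprints(roi_ts, sub$parcel_ts)
    sims[[s]] <- similarity_matrix(fp)
    fps[[s]] <- fp
    truth_subjects[[s]] <- sub$truth
    if (keep == "timeseries") {
      truth_subjects[[s]]$roi_ts <- sub$roi_ts
      truth_subjects[[s]]$parcel_ts <- sub$parcel_ts
    }
  }

  # coupled scores: correlation `r` with the age-residualized planted
  # parameter (the association is planted over and above age, as the
  # downstream analyses control for age), mapped onto the cohort table's
  # published moments
  by_planted <- vapply(truth_subjects, function(tr) tr$planted_tsm$left[["y"]], numeric(1))
  coupled <- function(param, r, mu, sd_, noise) {
    resid <- stats::lm.fit(cbind(1, cohort$age), param)$residuals
    zp <- as.vector(scale(resid))
    mu + sd_ * (r * zp + sqrt(1 - r^2) * noise)
  }
  sn <- cohort$score_noise
  covariates <- tibble::tibble(
    id = sprintf("sub-%04d", seq_len(n_subjects)),
    age = cohort$age, sex = cohort$sex, education = cohort$education,
    em_recollection = 1.58 + 0.69 * sn[, 1],
    em_recognition = coupled(by_planted, effects$em_coupling, 2.63, 0.55, sn[, 2]),
    em_priming = 0.41 + 0.09 * sn[, 3],
    er_reactivity = coupled(cohort$rostral_extent, effects$er_coupling, 5.29, 1.63, sn[, 4]),
    er_reappraisal = 0.038 + 1.11 * sn[, 5],
    hotel = pmax(10, 301.93 + 172.36 * sn[, 6]),
    psqi = cohort$psqi,
    hads = cohort$hads
  )

  truth <- list(subjects = truth_subjects,
                rostral_extent = cohort$rostral_extent,
                sharpness = cohort$sharpness,
                effects = effects, seed = seed)
  structure(list(covariates = covariates, sims = sims, fingerprints = fps,
                 coords = coords, mask = mask, truth = truth,
                 effects = effects, config = config, seed = seed,
                 fwhm_mm = fwhm_mm, exclude = integer(0)),
            class = "lc_cohort")
}

#' @export
print.lc_cohort <- function(x, ...) {
  cat(sprintf("<lc_cohort> %d subjects, %d ROI voxels, seed %d\n",
              nrow(x$covariates), nrow(x$coords), x$seed))
  print(x$covariates, n = 5)
  invisible(x)
}

#' Assemble a cohort from real volumetric inputs
#'
#' The real-data counterpart of [simulate_cohort()]: applies optional
#' nuisance regression and within-mask smoothing to each BOLD volume,
#' extracts ROI and parcel time series, and reduces each subject to
#' fingerprints and an eta-squared similarity matrix.
#'
#' @param bold_list list of [bold_volume()] (or file paths).
#' @param mask an [roi_mask()].
#' @param atlas an [atlas_labels()].
#' @param covariates tibble with one row per volume (must contain `id`,
#'   `age`, `sex`; score columns as available).
#' @param fwhm_mm within-mask smoothing FWHM (mm); the analyses in this
#'   package assume the gradient field is spatially smooth.
#' @param nuisance optional list of time x k matrices, one per subject.
#' @return An `lc_cohort`.
#' @export
cohort_from_volumes <- function(bold_list, mask, atlas, covariates,
                                fwhm_mm = 3, nuisance = NULL) {
  if (length(bold_list) != nrow(covariates)) {
    stopf("covariates must have one row per BOLD volume (%d vs %d)",
          nrow(covariates), length(bold_list))
  }
  coords <- coordinate_table(mask)
  sims <- vector("list", length(bold_list))
  fps <- vector("list", length(bold_list))
  exclude <- integer(0)
  for (s in seq_along(bold_list)) {
    bold <- bold_list[[s]]
    if (is.character(bold)) bold <- load_bold(bold)
    if (!is.null(nuisance)) bold <- regress_nuisance(bold, nuisance[[s]])
    roi <- extract_roi_timeseries(bold, mask)
    zv <- attr(roi$ts, "zero_variance")
    good <- setdiff(seq_len(nrow(roi$ts)), zv)
    roi_ts <- smooth_ts(roi$ts[good, , drop = FALSE],
                        coords[good, , drop = FALSE], fwhm_mm)
    parcel_ts <- extract_parcel_timeseries(bold, atlas)
    fp <- fingerprints(roi_ts, parcel_ts)
    S <- diag(nrow(roi$ts))
    S[good, good] <- similarity_matrix(fp)
    sims[[s]] <- S
    fp_full <- matrix(NA_real_, nrow(roi$ts), ncol(fp), dimnames = list(NULL, colnames(fp)))
    fp_full[good, ] <- fp
    fps[[s]] <- fp_full
    exclude <- union(exclude, zv)
  }
  structure(list(covariates = tibble::as_tibble(covariates), sims = sims,
                 fingerprints = fps, coords = coords, mask = mask,
                 truth = NULL, effects = NULL, config = NULL,
                 seed = NA_integer_, fwhm_mm = fwhm_mm,
                 exclude = sort(exclude)),
            class = "lc_cohort")
}
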