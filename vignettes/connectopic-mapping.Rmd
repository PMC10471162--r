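---
title: "Connectopic gradient mapping of the locus coeruleus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectopic gradient mapping of the locus coeruleus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcgrad)
```

## The problem

The locus coeruleus (LC) is a small bilateral noradrenergic nucleus in the
dorsolateral pons — a few dozen voxels at typical fMRI resolution. Its
cellular composition and its efferent projections are not homogeneous:
tracer and histology work shows the rostral part connecting preferentially
to limbic and associative targets (hippocampus, amygdala, medial temporal
and cingulate cortex) and the caudal part to sensorimotor and cerebellar
circuits. `lcgrad` maps this internal organization *functionally*, from
resting-state BOLD data alone, as a spatially continuous gradient of
connectivity change (a *connectopic map*), and provides the statistics
needed to relate that gradient's spatial layout to age, behavior, and
clinical screening scores.

## The gradient model

For each subject:

1. **Fingerprints.** Every ROI voxel's time series is correlated with the
   mean time series of every parcel of a whole-brain parcellation,
   producing a voxels x parcels matrix of Pearson correlations. Each row
   is that voxel's *connectivity fingerprint*.
2. **Eta-squared similarity.** Every pair of fingerprints `(a, b)` is
   scored with

   `eta2(a, b) = 1 - sum_i[(a_i - m_i)^2 + (b_i - m_i)^2] / sum_i[(a_i - M)^2 + (b_i - M)^2]`,

   where `m_i = (a_i + b_i)/2` and `M` is the grand mean of both profiles.
   `eta2` is 1 exactly for identical profiles and lies in `[0, 1]` always
   (the pointwise mean minimizes the squared deviations in the numerator).
3. **Connectivity-preserving graph.** The similarity matrix is thresholded
   at the *largest* value that still leaves the graph connected — the
   bottleneck edge weight of the maximum spanning tree, computed by a
   Prim sweep and verified in the tests against an exhaustive threshold
   scan; all retained edges keep their eta-squared weights. The threshold
   is recorded in every output so runs are auditable.
4. **Laplacian eigenmap.** The generalized eigenproblem
   `(D - W) v = lambda D v` is solved through the symmetric normalized
   Laplacian; the eigenvector with the smallest nonzero eigenvalue is the
   dominant gradient — the axis along which stepwise change in
   connectivity is largest. The trivial constant eigenvector at
   `lambda = 0` is discarded; a numerically repeated second eigenvalue
   (gap below 1e-10) triggers an instability warning.
5. **Orientation and scaling.** Eigenvector sign is arbitrary, so the
   gradient is flipped, if needed, to correlate positively with the
   anterior-posterior world coordinate (rostral = high) and min-max scaled
   to `[0, 1]`. Voxels above 0.5 form the rostral partition.

Hemispheres share one fingerprint/similarity computation but are
eigenmapped separately (left and right graphs), because the downstream
statistics analyze left and right spatial parameters as distinct
quantities. Group-level gradients average the similarity matrices
element-wise and decompose once; averaging per-subject eigenvectors would
require fragile sign/ordering alignment across subjects, which is exactly
the instability that motivates group-based estimation for an ROI this
small.

## Trend-surface summary

A gradient is a per-voxel scalar field; its spatial layout is summarized
per hemisphere by a third-order trend-surface model with the nine
pure-power terms `x, y, z, x^2, y^2, z^2, x^3, y^3, z^3` (no cross-terms)
over z-scored world coordinates, plus an unpenalized intercept that is
excluded from all downstream statistics. Coordinates are z-scored per
hemisphere so coefficients are comparable across hemispheres and across
phantoms of different physical size, and the left hemisphere's
medio-lateral axis is sign-flipped before z-scoring so "lateral" is
positive on both sides; a mirror-symmetric gradient therefore yields equal
left and right coefficients, which is tested.

The fit is an evidence-maximized Bayesian ridge (empirical Bayes): an
isotropic zero-mean Gaussian prior with precision `alpha` on the nine
coefficients and noise precision `beta`, both updated by the standard
effective-degrees-of-freedom fixed point until the change in `alpha` falls
below 1e-6 (at most 200 iterations; non-convergence is flagged, not
fatal). This choice is deterministic, reduces to least squares when the
data dominate, and shrinks gracefully when they do not. The per-iteration
log evidence is retained and tested to be non-decreasing. Left-right
asymmetry is quantified as the entrywise absolute coefficient difference
and its Euclidean norm.

## Cohort statistics

* **Sliding-window behavioral analysis.** Subjects are sorted by a
  behavioral score (ties broken by subject id), grouped into windows of 20
  slid by 5 (so n = 292 yields 55 windows), and each window's group
  gradient is summarized by the 18 bilateral trend-surface parameters. The
  window-mean score is regressed on those parameters over and above the
  window-mean nuisance covariates (age, sex, education) with a nested
  F-test; partial R-squared gets the Ezekiel-style small-sample
  adjustment. Post hoc, each parameter's partial Spearman correlation with
  the score (controlling the same covariates) is Benjamini-Hochberg
  adjusted across the 18 parameters (one FDR family per score).
* **Per-year age analysis.** Subjects are binned by integer year of age;
  each bin gets a group gradient and bilateral trend-surface fit; bin year
  is regressed on the 18 parameters over and above bin-mean sex, with the
  analogous partial Spearman post hocs.
* **Clusterability.** Each subject's own gradient is clustered by k-means
  (k = 2, Lloyd) and scored with the Calinski-Harabasz ratio
  `[B/(k-1)]/[W/(n-k)]`; the criterion is correlated with age by partial
  Spearman controlling sex. k-means is initialized deterministically at
  the first and third quartiles of the gradient values: a 1D two-cluster
  optimum is contiguous, quantile seeding finds it reliably, and the CH
  values become exactly reproducible.
* **Group contrast.** Subjects are stratified by the anxiety/depression
  screening score (abnormal if the score exceeds 7). Because such groups
  are usually imbalanced, equal-sized collections of group-average
  gradients are bootstrapped (20 subjects with replacement per iteration,
  1000 iterations by default), each reduced to its 18 parameters, and the
  two collections compared by one-way MANOVA (Pillai's trace) with
  per-parameter Mann-Whitney U post hocs under Benjamini-Hochberg
  correction.

Missing scores are deleted listwise per analysis, so different scores can
use different subsamples of the same cohort.

### Statistical caveats, stated plainly

Two properties of these published procedures deserve emphasis, and both
are documented by the test suite rather than hidden:

* The *windowed* F-test is anticonservative. Overlapping windows (15 of 20
  subjects shared between consecutive windows) make the parameter rows
  strongly autocorrelated while the sorted window-mean score is a smooth
  quantile trend; regressing the one on the other rejects a true null far
  above the nominal rate. The base nested F-test on independent rows is exactly
  calibrated, and that is what the calibration tests assert. Windowed
  p-values should be read as descriptive, and interpreted jointly with
  effect sizes (adjusted partial R-squared).
* The *bootstrap MANOVA* treats bootstrap replicates as independent
  observations. When the two pools are genuinely disjoint samples of the
  same population, the replicate clouds still separate by the
  cohort-level sampling error of each pool, which the within-cloud
  bootstrap variance does not reflect; the test then over-rejects
  (pseudo-replication). Its size is nominal when the two collections are
  generated by one identical process — the calibration test draws both
  groups' replicates from one shared pool for exactly this reason — and
  its use on disjoint groups is best read as a descriptive contrast with
  very high sensitivity.

## The phantom generator

All tests run on synthetic data with planted ground truth; nothing is
downloaded. The phantom emulates the *structure the analysis assumes*, not
realistic fMRI physics:

* **Geometry.** Two 48-voxel blobs (one per hemisphere) on a 20 x 20 x 30
  grid of 2 mm voxels: a 2 x 2 cross-section swept along 12
  anterior-posterior sections, drifting one voxel medially and dorsally
  every three sections. The curvature is anatomically motivated (the
  nucleus is not a straight block) and gives every axis enough distinct
  coordinate levels to identify all nine trend-surface terms. An atlas of
  12 "cortical" + 6 "subcortical" 3 x 3 x 3 parcels (a scaled-down
  analogue of a 360 + 50 parcellation) is placed clear of the ROI.
* **Planted field.** Each voxel has a rostro-caudal coordinate `t` in
  `[0, 1]` along a slightly oblique long axis (dominated by the
  anterior-posterior direction with small dorso-ventral and
  mirror-symmetric lateral components, so all 48 planted values are
  distinct). The planted caudal-ness is logistic,
  `g(t) = plogis(sharpness * (t - rostral_extent))`: the midpoint sits at
  the *rostral extent* (the fraction of the axis expressing rostral-like
  connectivity) and the steepness controls how clusterable the gradient
  is.
* **Signals.** With unit-variance latent series `s_rostral`, `s_caudal`
  (correlated 0.3 — distinct but not orthogonal profiles) and a global
  signal `s0`, each ROI voxel's series is
  `0.5 * s0 + (1 - g) * s_rostral + g * s_caudal + noise_sd * eps`.
  Rostral-target parcels carry `s_rostral`, caudal-target parcels
  `s_caudal`, and every parcel adds the global signal with its own loading
  (0.2 to 0.8, evenly spaced). The heterogeneous loadings matter: with
  only two pure target profiles every fingerprint collapses to two values,
  mid-gradient fingerprints become flat, and the eta-squared denominator
  degenerates — no spectral method can then order the voxels. Diverse
  baseline connectivity levels are also what real parcel profiles look
  like.
* **Cohorts.** Ages are uniform on 18-88. Per subject,
  `rostral_extent = 0.55 - 0.005 * (age - mean age) + N(0, 0.04)`,
  clipped to `[0, 1]` (rostral-like connectivity is lost with age), and
  the logistic sharpness is `8 + 0.06 * (age - mean age) + N(0, 0.6)`
  (the gradient becomes more clustered with age). Subjects whose
  screening score exceeds 7 lose a further 0.08 of rostral extent.
  Two behavioral scores are coupled (correlation 0.8) to planted spatial
  parameters *after residualizing on age* — the emotional-memory
  recognition score to the linear anterior-posterior coefficient and the
  emotional-reactivity score to the rostral extent — because the planted
  associations are meant to hold over and above age, which the analyses
  control for. All other scores are pure noise with first and second
  moments matching the cohort description table (education 14.56 (4.02)
  years, screening score median 5 on 0-20, and so on). Missingness is off
  by default; listwise deletion is exercised in tests by injecting it.

What the phantom does *not* emulate: autocorrelated or physiological
noise, scanner drift and artifacts, motion, registration error, or
spatially varying smoothness. Passing tests therefore demonstrate that
the estimation chain recovers the structure it assumes, at realistic
signal-to-noise — not that real LC data meet those assumptions.

## Numerical choices

* Smoothing within the mask uses the full (untruncated) Gaussian kernel
  between in-mask voxels in world coordinates, with per-voxel weight
  renormalization — constants are preserved exactly and no signal crosses
  the mask boundary. Note that boundary renormalization slightly perturbs
  near-tied orderings at the mask tips, which is why planted-field
  *recovery* is measured on the unsmoothed estimation chain while all
  cohort analyses keep the 3 mm smoothing of the study pipeline.
* Zero-variance voxels are excluded from correlation computations and
  their gradient value imputed as the mean of in-mask 6-neighbours
  (hemisphere mean as fallback), with a message.
* Grid or affine mismatches between inputs are hard errors; resampling is
  deliberately out of scope.
* Eigenvalues are clamped at zero; eigenvectors are D-orthonormal. Ties in
  the projection map's maximal correlation resolve to the first voxel in
  coordinate-table order, with a message.
* Degenerate trend-surface inputs (constant gradient) shrink all nine
  coefficients to zero with the constant in the intercept.

## Problem sizes used by the validation suite

The simulation-based tests and the acceptance script run at sizes chosen
to mirror the study design where that is what is being reproduced, and
scaled down where only calibration is at stake: sliding-window power at
n = 292 (the emotional-memory subsample, 55 windows), per-year age models
at n = 300, clusterability at n = 200, bootstrap contrasts with 200
iterations (default 1000), statistical calibration at 400 null replicates
(100 for the bootstrap, at 50 iterations), and planted-gradient recovery
over 20 seeds per noise level. Each power property is required in at
least 80% of 50 seeds at the generator defaults above.

## Known limitations

* Only the dominant gradient is analyzed; second and further eigenmaps
  are computed but not consumed.
* The analyses are cross-sectional; no longitudinal or mixed-effects
  modelling.
* Equivalence with any particular toolbox's Bayesian trend-surface
  numbers is not claimed; the prior scheme here is the package's own,
  documented above.
* The windowed and bootstrap procedures have the inferential caveats
  described earlier; they reproduce the published analysis design, not a
  recalibrated alternative.
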