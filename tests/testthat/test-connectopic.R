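test_that("eta-squared reproduces hand-derived values and identities", {
  expect_equal(eta_squared(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(eta_squared(c(1, 2), c(3, 4)), 0.2)        # 1 - 4/5
  expect_equal(eta_squared(c(1, -1), c(-1, 1)), 0)
  expect_warning(v <- eta_squared(c(2, 2), c(2, 2)), "identical")
  expect_equal(v, 1)
  expect_error(eta_squared(1, c(1, 2)), "equal length")
})

test_that("eta-squared is bounded, symmetric and maximal on the diagonal", {
  set.seed(1)
  for (i in 1:2000) {
    a <- rnorm(8); b <- rnorm(8)
    e <- eta_squared(a, b)
    expect_gte(e, 0); expect_lte(e, 1)
    expect_equal(e, eta_squared(b, a), tolerance = 1e-14)
  }
})

test_that("similarity_matrix matches the pairwise eta-squared loop", {
  set.seed(2)
  fp <- matrix(rnorm(6 * 10), 6, 10)
  S <- similarity_matrix(fp)
  for (i in 1:6) for (j in 1:6) {
    expected <- if (i == j) 1 else eta_squared(fp[i, ], fp[j, ])
    expect_equal(S[i, j], expected, tolerance = 1e-12)
  }
  expect_lt(max(abs(S - t(S))), 1e-12)

  # identical rows give the all-ones matrix
  expect_equal(similarity_matrix(matrix(rep(rnorm(5), each = 3), 3, 5)),
               matrix(1, 3, 3))

  # permutation equivariance
  perm <- sample(6)
  expect_equal(similarity_matrix(fp[perm, ]), S[perm, perm], tolerance = 1e-12)
})

test_that("graph threshold is the largest similarity preserving connectivity", {
  # uniform weights: threshold equals the common value, complete graph kept
  S <- matrix(0.5, 4, 4); diag(S) <- 1
  g <- build_connected_graph(S)
  expect_equal(g$threshold, 0.5)
  expect_true(all(g$W[upper.tri(g$W)] == 0.5))

  # 4-voxel chain: verify against an exhaustive scan over candidate thresholds
  S <- diag(4)
  S[1, 2] <- S[2, 3] <- S[3, 4] <- 0.9
  S[1, 3] <- S[2, 4] <- 0.5
  S[1, 4] <- 0.1
  S[lower.tri(S)] <- t(S)[lower.tri(S)]
  g <- build_connected_graph(S)
  cand <- sort(unique(S[upper.tri(S)]))
  connected <- vapply(cand, function(t) {
    A <- S >= t; diag(A) <- FALSE
    lcgrad:::adj_is_connected(A)
  }, logical(1))
  expect_equal(g$threshold, max(cand[connected]))
  expect_equal(g$threshold, 0.9)

  expect_true(isSymmetric(g$W))
  expect_true(all(diag(g$W) == 0))
  expect_true(lcgrad:::adj_is_connected(g$W > 0))
})

test_that("laplacian eigenmap matches a dense generalized solver", {
  # 5-node path: dominant eigenvector strictly monotone along the path
  W <- matrix(0, 5, 5)
  for (i in 1:4) W[i, i + 1] <- W[i + 1, i] <- 1
  es <- laplacian_eigenmap(structure(list(W = W, degrees = rowSums(W)),
                                     class = "similarity_graph"), 2)
  v <- es$vectors[, 1]
  expect_true(all(diff(v) > 0) || all(diff(v) < 0))
  expect_lt(es$lambda0, 1e-10)
  expect_true(all(es$values > 0))

  # triangle with weights (1, 1, eps) against the dense oracle
  W <- matrix(c(0, 1, 1e-3, 1, 0, 1, 1e-3, 1, 0), 3, 3)
  es <- laplacian_eigenmap(structure(list(W = W, degrees = rowSums(W)),
                                     class = "similarity_graph"), 2)
  oracle <- dense_eigen_oracle(W)
  expect_equal(es$values, oracle$values[2:3], tolerance = 1e-8)
  for (k in 1:2) {
    vo <- oracle$vectors[, k + 1]
    vo <- vo / sqrt(sum(vo^2 * rowSums(W)))          # D-normalize
    vi <- es$vectors[, k]
    expect_lt(min(max(abs(vi - vo)), max(abs(vi + vo))), 1e-6)
  }
})

test_that("eigenmap equals the dense oracle on random connected graphs", {
  set.seed(3)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    W <- random_connected_graph(n)
    # repeated eigenvalues legitimately trigger the instability warning here
    es <- suppressWarnings(
      laplacian_eigenmap(structure(list(W = W, degrees = rowSums(W)),
                                   class = "similarity_graph"),
                         n_components = min(3L, n - 1L)))
    oracle <- dense_eigen_oracle(W)
    k <- length(es$values)
    expect_equal(es$values, oracle$values[2:(k + 1)], tolerance = 1e-8)
    gaps <- diff(oracle$values)
    for (j in seq_len(k)) {
      # eigenvectors are only identified up to sign when the eigenvalue is
      # simple; skip numerically repeated eigenvalues
      if (gaps[j] < 1e-6 || (j + 1 <= length(gaps) && gaps[j + 1] < 1e-6)) next
      vo <- oracle$vectors[, j + 1]
      vo <- vo / sqrt(sum(vo^2 * rowSums(W)))
      vi <- es$vectors[, j]
      expect_lt(min(max(abs(vi - vo)), max(abs(vi + vo))), 1e-6)
    }
  }
})

test_that("orientation flips toward anterior and scales to [0, 1]", {
  sub <- noiseless_subject()
  co <- sub$coords[sub$coords$hemisphere == "left", ]
  v <- -(co$y) + rnorm(nrow(co), 0, 1e-6)
  out <- orient_and_scale(v, co)
  expect_true(attr(out, "flipped"))
  expect_gte(cor(out, co$y, method = "spearman"), 0.99)
  expect_equal(range(out), c(0, 1))
  # idempotence
  out2 <- orient_and_scale(as.numeric(out), co)
  expect_equal(as.numeric(out2), as.numeric(out), tolerance = 1e-12)
  expect_error(orient_and_scale(rep(1, nrow(co)), co), "constant")
})

test_that("group gradients reduce correctly for single and duplicated subjects", {
  coh <- small_cohort(8, seed = 21)
  g1 <- roi_gradient(coh$sims[[1]], coh$coords)
  expect_equal(group_gradient(coh$sims[1], coh$coords)$values, g1$values)
  expect_equal(group_gradient(coh$sims[c(2, 2, 2)], coh$coords)$values,
               roi_gradient(coh$sims[[2]], coh$coords)$values, tolerance = 1e-12)
})

test_that("voxel order permutations permute the gradient identically", {
  sub <- noiseless_subject()
  S <- similarity_matrix(fingerprints(sub$roi_ts, sub$parcel_ts))
  g <- roi_gradient(S, sub$coords)
  set.seed(4)
  perm <- sample(nrow(sub$coords))
  g2 <- roi_gradient(S[perm, perm], sub$coords[perm, ])
  expect_equal(g2$values, g$values[perm], tolerance = 1e-9)
})

test_that("rostral/caudal partition follows the 0.5 threshold rule", {
  expect_equal(partition_rostral_caudal(seq(0, 1, length.out = 10)),
               rep(c("caudal", "rostral"), each = 5))
  v <- c(0, rep(0.6, 8), 1)
  expect_equal(sum(partition_rostral_caudal(v) == "rostral"), 9L)
  # invariant to monotone rescaling preserving the 0.5 crossing
  v <- runif(30)
  mono <- function(x) ifelse(x > 0.5, 0.5 + (x - 0.5)^2, 0.5 - (0.5 - x)^2)
  expect_equal(partition_rostral_caudal(mono(v)), partition_rostral_caudal(v))
})

test_that("projection maps label parcels by their best-correlated voxel", {
  fp <- matrix(0.05, 4, 2, dimnames = list(NULL, c("p1", "p2")))
  fp[1, "p1"] <- 0.9
  fp[4, "p2"] <- 0.8
  labels <- c("rostral", "rostral", "caudal", "caudal")
  pm <- projection_map(fp, labels)
  expect_equal(pm$label, c("rostral", "caudal"))

  # mode across subjects
  fps <- list(fp, fp, fp)
  fps[[3]][1, "p1"] <- 0.01; fps[[3]][3, "p1"] <- 0.9
  pm3 <- projection_map(fps, list(labels, labels, labels))
  expect_equal(pm3$label[pm3$parcel == "p1"], "rostral")

  # ties are logged and resolved to the first voxel in coordinate order
  fp_tie <- matrix(c(0.5, 0.5, 0.1, 0.1), 4, 1)
  expect_message(pm_tie <- projection_map(fp_tie, labels), "tie")
  expect_equal(pm_tie$label, "rostral")
})

test_that("noiseless phantom target parcels project to their planted side", {
  sub <- noiseless_subject()
  fp <- fingerprints(sub$roi_ts, sub$parcel_ts)
  g <- roi_gradient(similarity_matrix(fp), sub$coords)
  pm <- projection_map(fp, partition_rostral_caudal(g))
  expect_equal(pm$label, sub$atlas$labels$target)
})

test_that("a monotone gradient yields a contiguous partition boundary", {
  sub <- noiseless_subject()
  g <- roi_gradient(similarity_matrix(fingerprints(sub$roi_ts, sub$parcel_ts)),
                    sub$coords)
  lab <- partition_rostral_caudal(g)
  tcoord <- lcgrad:::rostrocaudal_coordinate(sub$coords)
  for (h in c("left", "right")) {
    sel <- sub$coords$hemisphere == h
    ord <- order(tcoord[sel])
    runs <- rle(lab[sel][ord])
    expect_equal(length(runs$lengths), 2L)
    expect_equal(runs$values, c("rostral", "caudal"))
  }
})
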