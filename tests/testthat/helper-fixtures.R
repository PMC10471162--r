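# Shared fixtures, cached per test run so expensive phantoms are built once.
.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

noiseless_subject <- function(seed = 7) {
  fixture(paste0("sub0_", seed),
          simulate_subject(phantom_config(noise_sd = 0), format = "timeseries",
                           seed = seed))
}

small_cohort <- function(n = 40, seed = 3) {
  fixture(sprintf("cohort_%d_%d", n, seed),
          simulate_cohort(n, seed = seed))
}

# independent dense solver for the generalized eigenproblem (D - W) v = lambda D v
dense_eigen_oracle <- function(W) {
  d <- rowSums(W)
  L <- diag(d) - W
  es <- eigen(solve(diag(d)) %*% L)
  ord <- order(Re(es$values))
  list(values = Re(es$values)[ord], vectors = Re(es$vectors)[, ord, drop = FALSE])
}

# random connected weighted graph on n nodes (spanning tree + extra edges)
random_connected_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample.int(i - 1L, 1L)
    W[i, j] <- W[j, i] <- runif(1, 0.2, 1)
  }
  extra <- which(upper.tri(W) & W == 0)
  if (length(extra)) {
    pick <- sample(extra, size = min(length(extra), n))
    W[pick] <- runif(length(pick), 0, 1) * (runif(length(pick)) < 0.5)
    W[lower.tri(W)] <- t(W)[lower.tri(W)]
  }
  W
}
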