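stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Apply a 4x4 affine to 0-based voxel indices
#'
#' @param affine 4x4 voxel-to-world transform.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @keywords internal
apply_affine <- function(affine, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3L)
  xyz <- cbind(ijk, 1) %*% t(affine[1:3, , drop = FALSE])
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  xyz
}

# Breadth-first connectivity of a symmetric logical adjacency matrix.
# Diagonal is ignored. Returns TRUE iff the graph is a single component.
adj_is_connected <- function(adj) {
  n <- nrow(adj)
  if (n <= 1L) return(TRUE)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    reach <- if (length(frontier) == 1L) adj[, frontier] else rowSums(adj[, frontier, drop = FALSE]) > 0
    new <- which(reach & !seen)
    seen[new] <- TRUE
    frontier <- new
  }
  all(seen)
}

affines_match <- function(a, b, tol = 1e-4) {
  max(abs(a - b)) <= tol
}

check_compatible <- function(dim_a, affine_a, dim_b, affine_b, what = "volumes") {
  if (!identical(as.integer(dim_a[1:3]), as.integer(dim_b[1:3]))) {
    stopf("Incompatible %s: grid %s vs %s", what,
          paste(dim_a[1:3], collapse = "x"), paste(dim_b[1:3], collapse = "x"))
  }
  if (!affines_match(affine_a, affine_b)) {
    stopf("Incompatible %s: affines differ by more than 1e-4 mm.\nFirst:\n%s\nSecond:\n%s",
          what,
          paste(utils::capture.output(print(affine_a)), collapse = "\n"),
          paste(utils::capture.output(print(affine_b)), collapse = "\n"))
  }
  invisible(TRUE)
}

# Local RNG scope: run `expr` under `seed` without disturbing the caller's
# RNG stream. Seeds must stay below 2^31 (R integers).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
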