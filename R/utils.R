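# Internal numerical helpers shared across the package.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the Mersenne-Twister generator, runs
#' `expr`, and restores the previous state on exit, so that seeded package
#' functions never clobber the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Flip the sign of a vector so its largest-magnitude entry is positive.
# Deterministic convention: ties resolved by the first maximal index.
fix_sign <- function(v) {
  i <- which.max(abs(v))
  if (v[i] < 0) -v else v
}

unitize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot normalize a zero vector")
  v / nv
}

# Angle between two nonzero vectors modulo sign, in radians, in [0, pi/2].
angle_mod_sign <- function(a, b) {
  ca <- abs(sum(unitize(a) * unitize(b)))
  acos(min(1, ca))
}

# Numerical rank of a matrix from its singular values (LAPACK-style tolerance).
matrix_rank <- function(m, tol = NULL) {
  s <- svd(m, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(m)) * .Machine$double.eps * max(s)
  sum(s > tol)
}

# Symmetric-definite generalized eigenproblem A v = lambda B v, A symmetric,
# B symmetric positive definite.  Solved in the B-inner-product via the
# Cholesky factor of B (never via an explicit B^-1 A), returning eigenvalues
# in increasing order and B-orthonormal eigenvectors.
sym_geigen <- function(A, B) {
  A <- (A + t(A)) / 2
  B <- (B + t(B)) / 2
  U <- tryCatch(chol(B), error = function(e) {
    stop("right-hand matrix of the generalized eigenproblem is not positive definite")
  })
  # M = U^-T A U^-1, symmetric; v = U^-1 y
  M <- backsolve(U, t(backsolve(U, t(A), transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]
  vecs <- backsolve(U, e$vectors[, ord, drop = FALSE])
  list(values = vals, vectors = vecs)
}

# Smallest-eigenpair extraction with a relative-degeneracy flag.
smallest_eigenpair <- function(values, vectors, rel_tol = 1e-10) {
  v <- unitize(vectors[, 1L])
  degenerate <- FALSE
  if (length(values) > 1L) {
    gap <- values[2L] - values[1L]
    scale <- max(abs(values[1L]), abs(values[2L]))
    degenerate <- is.finite(gap) && gap <= rel_tol * scale
  }
  list(value = values[1L], vector = fix_sign(v), degenerate = degenerate)
}

# Inverse symmetric square root of a positive definite matrix.
inv_sqrt_pd <- function(N) {
  N <- (N + t(N)) / 2
  e <- eigen(N, symmetric = TRUE)
  if (min(e$values) <= 0)
    stop("matrix is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

as_cov_matrix <- function(R) {
  if (inherits(R, "second_moment")) R$R else as.matrix(R)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
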