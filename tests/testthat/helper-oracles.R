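# Test helpers: independent oracles and small fixture builders.

unit <- function(v) v / sqrt(sum(v^2))

# Angle between two vectors modulo sign, in radians.
angle_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  acos(min(1, abs(sum(a * b))))
}

# Quasi-uniform unit vectors: Fibonacci lattice on S^2, half-circle in 2-d
# (orientations are sign-symmetric).
unit_vector_scan <- function(p, n) {
  if (p == 3L) {
    i <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
  } else {
    th <- pi * (seq_len(n) - 0.5) / n
    cbind(cos(th), sin(th))
  }
}

# Brute-force orientation oracle: minimize the Rayleigh quotient
# eta' A eta / eta' B eta over the unit sphere by scanning, then polishing
# with Nelder-Mead on spherical angles.  Independent of the package's
# Cholesky-based symmetric-definite eigen path.
brute_min_rayleigh <- function(A, B, n_scan = 20000L) {
  p <- ncol(A)
  q <- function(v) {
    v <- v / sqrt(sum(v^2))
    sum(v * (A %*% v)) / sum(v * (B %*% v))
  }
  V <- unit_vector_scan(p, n_scan)
  vals <- rowSums((V %*% A) * V) / rowSums((V %*% B) * V)
  v0 <- V[which.min(vals), ]
  if (p == 3L) {
    par0 <- c(atan2(v0[2], v0[1]), asin(max(-1, min(1, v0[3]))))
    fn <- function(par) q(c(cos(par[2]) * cos(par[1]),
                            cos(par[2]) * sin(par[1]), sin(par[2])))
    opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 5000))
    opt <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                        control = list(reltol = 1e-16, maxit = 5000))
    par <- opt$par
    v <- c(cos(par[2]) * cos(par[1]), cos(par[2]) * sin(par[1]), sin(par[2]))
  } else {
    th0 <- atan2(v0[2], v0[1])
    fn <- function(th) q(c(cos(th), sin(th)))
    opt <- stats::optimize(fn, c(th0 - 0.01, th0 + 0.01), tol = 1e-12)
    v <- c(cos(opt$minimum), sin(opt$minimum))
  }
  v / sqrt(sum(v^2))
}

# Non-symmetric oracle for the generalized eigenproblem: eigen(B^-1 A),
# smallest real eigenvalue (the spec form nu_min(B^-1 A)).
geigen_oracle <- function(A, B) {
  e <- eigen(solve(B, A))
  vals <- Re(e$values)
  v <- Re(e$vectors[, which.min(vals)])
  v / sqrt(sum(v^2))
}

# Random symmetric positive definite matrix.
random_pd <- function(n) {
  G <- matrix(rnorm(n * n), n)
  crossprod(G) / n + diag(n)
}

# Small MEG-like fixture frame plus a ground-truth orientation with both
# tangential and radial content.
fixture_case <- function(seed, n_channels = 24L, sv = c(1, 0.6, 0.1)) {
  lf <- generate_synthetic_leadfield(n_channels, sv, seed = seed,
                                     modality = "MEG")
  frame <- make_target_frame(lf)
  eta <- drop(sample_random_orientations(1L, seed + 5000L))
  list(lf = lf, frame = frame, eta = eta,
       x = drop(lf$matrix %*% eta))
}

tangential_of <- function(frame, v) {
  c(sum(frame$vt1 * v), sum(frame$vt2 * v))
}
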