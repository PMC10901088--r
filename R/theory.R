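# Closed-form reconstruction theory for the single-source model: limiting
# Unit-Gain orientations, the rank-one secular equation, and the pseudo-Z /
# neural-activity-index scores with their pre-whitening equivalences.

#' High-noise limit of the Unit-Gain orientation estimate
#'
#' As the noise power grows, the Unit-Gain reconstruction converges (up to
#' sign) to the eigenvector of `L' N0^-1 L` belonging to the smallest
#' eigenvalue, where `N0` is the shape of the noise covariance.  For
#' isotropic noise (`N0 = I`, the default) this is the right singular
#' vector of the leadfield with the smallest singular value -- the estimate
#' is then determined entirely by the leadfield, not by the data.
#'
#' @param leadfield a [leadfield] or full-column-rank matrix (channels x 3,
#'   or channels x 2 for a reduced MEG leadfield).
#' @param N0 optional positive definite noise-shape matrix; identity when
#'   missing.
#' @return unit orientation vector, sign-fixed.  Errors if the smallest
#'   eigenvalue is degenerate (the limit is then not unique).
#' @export
ug_high_noise_limit <- function(leadfield, N0 = NULL) {
  L <- if (inherits(leadfield, "leadfield")) leadfield$matrix
       else base::as.matrix(leadfield)
  if (!all(is.finite(L))) stop("non-finite leadfield")
  if (matrix_rank(L) < ncol(L)) stop("rank-deficient leadfield")
  A <- if (is.null(N0)) {
    crossprod(L)
  } else {
    N0 <- base::as.matrix(N0)
    S <- tryCatch(solve((N0 + t(N0)) / 2, L),
                  error = function(e) stop("N0 is singular"))
    crossprod(L, S)
  }
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  ord <- order(e$values)
  sm <- smallest_eigenpair(e$values[ord], e$vectors[, ord, drop = FALSE])
  if (sm$degenerate)
    stop("smallest eigenvalue of L' N0^-1 L is degenerate; the high-noise limit is not unique")
  sm$vector
}

#' Solve the rank-one secular equation of the reduced MEG eigenproblem
#'
#' The smallest eigenvalue of the diagonal-minus-rank-one matrix governing
#' the Unit-Gain reconstruction in the tangential plane is the unique root
#' `lambda < s2^2` of
#' \deqn{\frac{(s_1^2 \eta_{t1})^2}{s_1^2 - \lambda} +
#'       \frac{(s_2^2 \eta_{t2})^2}{s_2^2 - \lambda} = \alpha,}
#' the classic secular equation of a symmetric rank-one update.  The left
#' side is positive and strictly increasing on `(-Inf, s2^2)`, so the root
#' exists, is unique, and increases strictly with the right-hand side.
#'
#' Because the root can lie arbitrarily close to the pole at `s2^2` (when
#' one tangential coefficient is small), the equation is solved in the
#' pole-free gap variable `delta = s2^2 - lambda > 0` by safeguarded
#' geometric bisection; the gap is returned alongside `lambda` (attribute
#' `"gap"`) at full relative precision, which the eigenvector formula and
#' residual checks should use in place of the cancellation-prone
#' difference `s2^2 - lambda`.
#'
#' @param s1,s2 singular values of the reduced MEG leadfield, `s1 >= s2 > 0`.
#' @param eta_t tangential ground-truth coefficients `(eta_t1, eta_t2)`,
#'   not both zero.
#' @param rhs positive right-hand side: `alpha = (sigma^2 + ||x||^2) / Q^2`
#'   at finite noise, or `||LM eta_sim||^2` at the low-noise limit.
#' @param tol residual tolerance, relative to `rhs`.
#' @param max_iter iteration cap for the bisection.
#' @return the root `lambda` (a scalar `< s2^2`), with the gap
#'   `s2^2 - lambda` attached as attribute `"gap"`.
#' @export
solve_secular <- function(s1, s2, eta_t, rhs, tol = 1e-12, max_iter = 200L) {
  stopifnot(s1 >= s2, s2 > 0, rhs > 0)
  z1 <- (s1^2 * eta_t[1L])^2
  z2 <- (s2^2 * eta_t[2L])^2
  if (z1 == 0 && z2 == 0) stop("tangential coefficients must not both be zero")
  d <- s1^2 - s2^2
  if (z2 == 0) {
    # single pole at s1^2: s1^2 - lambda = z1 / rhs exactly
    lam <- s1^2 - z1 / rhs
    return(structure(lam, gap = d + z1 / rhs))
  }
  # g(delta) = z1 / (d + delta) + z2 / delta is strictly decreasing on
  # (0, Inf) from +Inf to 0, so the root brackets cleanly.
  g <- function(delta) z1 / (d + delta) + z2 / delta
  lo <- z2 / rhs                       # g(lo) >= rhs (exact root when z1 = 0)
  hi <- lo
  while (g(hi) > rhs) hi <- hi * 2
  delta <- hi
  for (i in seq_len(max_iter)) {
    delta <- sqrt(lo * hi)             # geometric step spans magnitudes fast
    gd <- g(delta)
    if (abs(gd - rhs) <= tol * rhs) break
    if (gd > rhs) lo <- delta else hi <- delta
    if ((hi - lo) <= .Machine$double.eps * hi) break
  }
  structure(s2^2 - delta, gap = delta)
}

# Shared closed-form expected UG reconstruction in the tangential plane for
# a given secular right-hand side alpha.  Handles the diagonal cases where
# one tangential coefficient vanishes.
expected_ug_tangential <- function(frame, eta_sim, alpha) {
  stopifnot(inherits(frame, "target_frame"))
  if (frame$degenerate)
    stop("s1 = s2 (degenerate tangential spectrum); the closed form assumes distinct singular values")
  s <- frame$singular_values
  eta <- unitize(as.numeric(eta_sim))
  et <- tangential_component(frame, eta)
  if (sqrt(sum(et^2)) < 1e-12)
    stop("purely radial orientation: no tangential component to reconstruct")
  if (abs(et[1L]) < 1e-15 || abs(et[2L]) < 1e-15) {
    # Diagonal matrix diag(s1^2, s2^2) minus a rank-one term on one axis only.
    i <- if (abs(et[1L]) >= abs(et[2L])) 1L else 2L
    d <- s[1:2]^2
    d[i] <- d[i] - (s[i]^2 * et[i])^2 / alpha
    out <- if (d[1L] <= d[2L]) c(1, 0) else c(0, 1)
    return(fix_sign(out))
  }
  lam <- solve_secular(s[1L], s[2L], et, alpha)
  delta <- attr(lam, "gap")            # s2^2 - lambda at full precision
  v <- c(s[1L]^2 * et[1L] / (s[1L]^2 - s[2L]^2 + delta),
         s[2L]^2 * et[2L] / delta)
  fix_sign(unitize(v))
}

#' Low-noise limit of the MEG Unit-Gain tangential reconstruction
#'
#' Unlike the EEG case, the MEG Unit-Gain estimate does not converge to the
#' (normalized) tangential component of the truth as the noise vanishes.
#' Because the covariance contains the full gain `LM eta_sim` while the
#' reconstruction uses the tangentially reduced leadfield, the limit is
#' \deqn{\tilde\eta = c \left(\frac{s_1^2 \eta_{t1}}{s_1^2 - \lambda_0},
#'       \frac{s_2^2 \eta_{t2}}{s_2^2 - \lambda_0}\right),}
#' with `lambda0` the secular root for right-hand side `||LM eta_sim||^2`
#' and `c` a normalizing constant.  When the leadfield has no radial
#' component (`s3 = 0`) or the truth is purely tangential, `lambda0 = 0`
#' and the limit collapses to the normalized tangential truth.
#'
#' @param meg_frame a [target_frame] with distinct `s1 != s2`.
#' @param eta_sim ground-truth unit 3-vector with nonzero tangential part.
#' @return unit 2-vector of tangential coefficients, sign-fixed.
#' @export
meg_low_noise_limit <- function(meg_frame, eta_sim) {
  s <- meg_frame$singular_values
  eta <- unitize(as.numeric(eta_sim))
  et <- tangential_component(meg_frame, eta)
  er <- radial_component(meg_frame, eta)
  rhs <- (s[1L] * et[1L])^2 + (s[2L] * et[2L])^2 + (s[3L] * er)^2  # ||LM eta||^2
  expected_ug_tangential(meg_frame, eta, rhs)
}

#' Expected Unit-Gain tangential reconstruction at finite noise
#'
#' Closed-form population-covariance Unit-Gain estimate in the tangential
#' plane at noise power `sigma^2`, via the secular root for
#' `alpha = (sigma^2 + ||x||^2) / Q^2` with `x = Q LM eta_sim`.  As
#' `sigma -> 0` this reproduces [meg_low_noise_limit()]; as `sigma -> Inf`
#' it converges to the axis of the smaller reduced singular value.
#'
#' @param meg_frame a [target_frame] with distinct `s1 != s2`.
#' @param eta_sim ground-truth unit 3-vector with nonzero tangential part.
#' @param Q2 source power (default 0.5, the normalized sinusoid's power).
#' @param sigma2 noise power `sigma^2 >= 0`.
#' @return unit 2-vector of tangential coefficients, sign-fixed.
#' @export
expected_ug_finite_noise <- function(meg_frame, eta_sim, Q2 = 0.5, sigma2) {
  stopifnot(Q2 > 0, sigma2 >= 0)
  s <- meg_frame$singular_values
  eta <- unitize(as.numeric(eta_sim))
  et <- tangential_component(meg_frame, eta)
  er <- radial_component(meg_frame, eta)
  norm_L_eta2 <- (s[1L] * et[1L])^2 + (s[2L] * et[2L])^2 + (s[3L] * er)^2
  alpha <- sigma2 / Q2 + norm_L_eta2   # (sigma^2 + Q^2 ||L eta||^2) / Q^2
  expected_ug_tangential(meg_frame, eta, alpha)
}

#' Pseudo-Z and neural-activity-index scores of a gain vector
#'
#' Noise-normalized beamformer power scores for the gain vector `l` under
#' data covariance `R` and noise covariance `N`:
#' \deqn{Z = \frac{w' R w}{w' N w}, \qquad
#'       NAI = \frac{l' N^{-1} l}{l' R^{-1} l},}
#' with `w` the minimum-variance filter `R^-1 l` (the pseudo-Z is invariant
#' to the filter's scale).  Also returns the projected power `w' R w` of the
#' UG, UNG and AG filters on the original quantities and on the pre-whitened
#' quantities (`N^-1/2` applied to signal space), which exhibit the
#' equivalences: pre-whitened AG power equals the NAI, pre-whitened UNG
#' power equals the pseudo-Z, and for isotropic `N = sigma^2 I` the plain AG
#' power equals `sigma^2` times the NAI.
#'
#' @param l gain vector in channel space.
#' @param R a `second_moment` object or symmetric positive definite matrix.
#' @param N noise covariance matrix (symmetric positive definite).
#' @return object of class `bf_scores`: list with `pseudo_z`, `nai`,
#'   `projected_power` and `whitened_power` (named vectors over UG/UNG/AG),
#'   and the whitening transform `whitener` (`N^-1/2`).
#' @export
beamformer_scores <- function(l, R, N) {
  l <- as.numeric(l)
  Rm <- as_cov_matrix(R)
  N <- base::as.matrix(N)
  W <- inv_sqrt_pd(N)                  # errors if N is not PD
  evR <- eigen((Rm + t(Rm)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(evR) <= 0) stop("covariance R must be positive definite")
  sol <- solve(Rm, l)
  pseudo_z <- sum(l * sol) / drop(crossprod(sol, N %*% sol))
  nai <- drop(crossprod(l, solve(N, l))) / sum(l * sol)
  power_of <- function(lv, Rv) {
    vapply(c("UG", "UNG", "AG"), function(m) {
      w <- compute_filter(lv, Rv, m)$w
      drop(crossprod(w, Rv %*% w))
    }, numeric(1))
  }
  lw <- drop(W %*% l)
  Rw <- W %*% Rm %*% W
  Rw <- (Rw + t(Rw)) / 2
  structure(
    list(pseudo_z = pseudo_z, nai = nai,
         projected_power = power_of(l, Rm),
         whitened_power = power_of(lw, Rw),
         whitener = W),
    class = "bf_scores"
  )
}

#' @export
print.bf_scores <- function(x, ...) {
  cat(sprintf("<bf_scores> pseudo-Z %.6g, NAI %.6g\n", x$pseudo_z, x$nai))
  cat("  projected power:", paste(names(x$projected_power),
                                  signif(x$projected_power, 6),
                                  sep = "=", collapse = " "), "\n")
  invisible(x)
}
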