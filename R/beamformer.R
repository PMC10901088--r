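# Covariance estimation, the three scalar LCMV filters, the orientation
# eigenproblems, EEG-MEG fusion, and the angular error metric.

new_second_moment <- function(R, source, T_used, regularization_fraction,
                              regularized) {
  structure(
    list(R = R, source = source, T_used = T_used,
         regularization_fraction = regularization_fraction,
         regularized = regularized),
    class = "second_moment"
  )
}

#' @export
print.second_moment <- function(x, ...) {
  cat(sprintf("<second_moment> %d x %d, %s%s%s\n",
              nrow(x$R), ncol(x$R), x$source,
              if (!is.na(x$T_used)) sprintf(", T = %d", x$T_used) else "",
              if (x$regularized)
                sprintf(", regularized %.3g", x$regularization_fraction)
              else ""))
  invisible(x)
}

#' Estimate the second-moment (covariance) matrix from sensor data
#'
#' Computes the time-averaged outer product `R = (1/T) sum_t d(t) d(t)'`
#' with no mean subtraction -- for the zero-mean sinusoidal sources
#' simulated here this equals the covariance matrix.  Diagonal loading is
#' applied in the trace-scaled convention common to beamformer toolboxes:
#' with fraction `lambda > 0`,
#' `R = R_raw + lambda (trace(R_raw) / n) I`, which also guarantees strict
#' positive definiteness.
#'
#' @param data a `simulated_data` object or a channels x T numeric matrix.
#' @param regularization_fraction diagonal-loading fraction `lambda`
#'   (default 0.05, the 5\% used throughout the simulation experiments).
#' @return a `second_moment` object.
#' @export
estimate_covariance <- function(data, regularization_fraction = 0.05) {
  X <- if (inherits(data, "simulated_data")) data$samples else base::as.matrix(data)
  if (!all(is.finite(X))) stop("non-finite data")
  if (ncol(X) < 2L) stop("need at least 2 time samples")
  if (regularization_fraction < 0) stop("regularization fraction must be >= 0")
  T_used <- ncol(X)
  R <- tcrossprod(X) / T_used
  R <- (R + t(R)) / 2
  regularized <- regularization_fraction > 0
  if (regularized)
    R <- R + diag(regularization_fraction * sum(diag(R)) / nrow(R), nrow(R))
  new_second_moment(R, source = "sample", T_used = T_used,
                    regularization_fraction = regularization_fraction,
                    regularized = regularized)
}

#' Compute a scalar LCMV spatial filter for a fixed orientation
#'
#' Minimum-variance filters `w` for the gain vector `l = L eta`, under the
#' three pass constraints that define the beamformer variants:
#' \describe{
#'   \item{UG (unit gain)}{`w' l = 1`; `w = R^-1 l / (l' R^-1 l)`.}
#'   \item{UNG (unit noise gain)}{`||w|| = 1`;
#'     `w = R^-1 l / sqrt(l' R^-2 l)`.}
#'   \item{AG (array gain)}{`w' l = ||l||`;
#'     `w = R^-1 lt / (lt' R^-1 lt)` with `lt = l / ||l||`.}
#' }
#' Solved via linear systems on the (regularized or analytic) covariance,
#' never by forming an explicit inverse.
#'
#' @param l gain vector in channel space (`L eta`), nonzero.
#' @param R a `second_moment` object or symmetric positive definite matrix.
#' @param method `"UG"`, `"UNG"` or `"AG"`.
#' @return object of class `bf_filter`: list with `w`, `method`,
#'   `gain_direction`.
#' @export
compute_filter <- function(l, R, method = c("UG", "UNG", "AG")) {
  method <- match.arg(method)
  l <- as.numeric(l)
  if (sqrt(sum(l^2)) == 0) stop("zero gain vector")
  Rm <- as_cov_matrix(R)
  sol <- tryCatch(solve(Rm, l), error = function(e) stop("singular covariance matrix"))
  w <- switch(method,
    UG  = sol / sum(l * sol),
    UNG = sol / sqrt(sum(sol^2)),
    AG  = {
      nl <- sqrt(sum(l^2))
      (sol / nl) / (sum(l * sol) / nl^2)
    })
  structure(list(w = w, method = method, gain_direction = l),
            class = "bf_filter")
}

#' Estimate a source orientation by solving the beamformer eigenproblem
#'
#' The power-maximizing orientation of each beamformer variant is the
#' eigenvector of the smallest (generalized) eigenvalue of
#' \describe{
#'   \item{UG}{`L' R^-1 L` (ordinary symmetric eigenproblem),}
#'   \item{UNG}{the pair `(L' R^-2 L, L' R^-1 L)`,}
#'   \item{AG}{the pair `(L' R^-1 L, L' L)`.}
#' }
#' Generalized problems are solved in symmetric-definite form through the
#' Cholesky factor of the right-hand matrix.  The returned vector is unit
#' norm with its largest-magnitude component positive.  A degeneracy flag is
#' set when the smallest eigenvalue is within relative 1e-10 of the next
#' one, in which case the eigenvector is an arbitrary member of the
#' eigenspace.
#'
#' @param leadfield a [leadfield], a channels x 3 matrix, or a channels x 2
#'   tangentially reduced MEG leadfield; must have full column rank.
#' @param R a `second_moment` object or symmetric positive definite matrix.
#' @param method `"UG"`, `"UNG"` or `"AG"`.
#' @param modality optional tag stored on the estimate (`"EEG"`, `"MEG"`,
#'   `"EMEG"`); inferred from the column count when missing.
#' @return object of class `orientation_estimate`: list with `eta_hat`
#'   (unit vector, 3-d or 2-d), `method`, `modality`,
#'   `smallest_eigenvalue`, `eigenvalues` and `degenerate`.
#' @examples
#' L <- generate_synthetic_leadfield(20, c(1, 0.6, 0.1), seed = 3)
#' eta <- c(1, 0, 0)
#' R <- analytic_covariance(L$matrix %*% eta, 0.5, sigma2 = 1e-12)
#' estimate_orientation(L, R, "UNG")$eta_hat
#' @export
estimate_orientation <- function(leadfield, R, method = c("UG", "UNG", "AG"),
                                 modality = NULL) {
  method <- match.arg(method)
  L <- if (inherits(leadfield, "leadfield")) leadfield$matrix
       else base::as.matrix(leadfield)
  if (!all(is.finite(L))) stop("non-finite leadfield")
  p <- ncol(L)
  if (!p %in% c(2L, 3L)) stop("leadfield must have 2 or 3 columns")
  if (matrix_rank(L) < p) stop("rank-deficient leadfield")
  if (is.null(modality)) modality <- if (p == 2L) "MEG" else "EEG"
  Rm <- as_cov_matrix(R)
  S <- tryCatch(solve(Rm, L), error = function(e) stop("singular covariance matrix"))
  A1 <- crossprod(L, S)               # L' R^-1 L
  A1 <- (A1 + t(A1)) / 2
  eig <- switch(method,
    UG = {
      e <- eigen(A1, symmetric = TRUE)
      ord <- order(e$values)
      list(values = e$values[ord], vectors = e$vectors[, ord, drop = FALSE])
    },
    UNG = sym_geigen(crossprod(S), A1), # (L' R^-2 L, L' R^-1 L)
    AG  = sym_geigen(A1, crossprod(L))  # (L' R^-1 L, L' L)
  )
  sm <- smallest_eigenpair(eig$values, eig$vectors)
  structure(
    list(eta_hat = sm$vector, method = method, modality = modality,
         smallest_eigenvalue = sm$value, eigenvalues = eig$values,
         degenerate = sm$degenerate),
    class = "orientation_estimate"
  )
}

#' @export
print.orientation_estimate <- function(x, ...) {
  cat(sprintf("<orientation_estimate> %s/%s: (%s)%s\n",
              x$method, x$modality,
              paste(sprintf("%.4f", x$eta_hat), collapse = ", "),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Fuse a tangential MEG estimate with an EEG estimate
#'
#' Combined EEG-MEG orientation: the tangential part comes from the MEG
#' estimate (MEG is most sensitive in the tangential plane and barely
#' affected by conductivity errors), the radial part from the EEG estimate.
#' With `r` the radial component of the EEG estimate, the MEG tangential
#' unit 2-vector is scaled by `sqrt(1 - r^2)`, embedded via `(vt1, vt2)`,
#' superposed with `r vr` and normalized.  Because beamformer estimates are
#' sign-blind, the MEG/EEG relative sign is resolved by maximizing agreement
#' with the EEG estimate's own tangential part (falling back to a positive
#' first tangential coefficient when the EEG estimate is purely radial).
#' If the EEG estimate is exact and the MEG estimate equals the normalized
#' tangential truth up to sign, the fused output is the truth up to sign.
#'
#' @param eta_meg_tangential unit 2-vector of tangential coefficients.
#' @param eta_eeg unit 3-vector (full EEG orientation estimate).
#' @param frame the [target_frame] defining `(vt1, vt2, vr)`.
#' @return unit 3-vector, sign-fixed.
#' @export
fuse_emeg <- function(eta_meg_tangential, eta_eeg, frame) {
  stopifnot(inherits(frame, "target_frame"))
  tm <- as.numeric(eta_meg_tangential)
  he <- as.numeric(eta_eeg)
  if (length(tm) != 2L || length(he) != 3L)
    stop("expected a tangential 2-vector and a full 3-vector")
  if (abs(sqrt(sum(tm^2)) - 1) > 1e-6 || abs(sqrt(sum(he^2)) - 1) > 1e-6)
    stop("inputs must be unit vectors")
  tm <- unitize(tm)
  he <- unitize(he)
  r <- radial_component(frame, he)
  te <- tangential_component(frame, he)
  s <- if (sqrt(sum(te^2)) < 1e-9) {
    if (tm[which.max(abs(tm))] < 0) -1 else 1
  } else if (sum(tm * te) < 0) -1 else 1
  tang <- s * tm * sqrt(max(0, 1 - r^2))
  out <- tang[1L] * frame$vt1 + tang[2L] * frame$vt2 + r * frame$vr
  fix_sign(unitize(out))
}

#' Angular orientation-estimation error in degrees
#'
#' The error metric `epsilon = arccos(|eta_hat' eta_true|) * 180 / pi`,
#' which ranges from 0 (estimate parallel or anti-parallel to the truth --
#' beamformers cannot distinguish the sign) to 90 degrees (orthogonal).
#' For tangential-plane MEG scoring pass two 2-vectors; both inputs are
#' normalized internally.
#'
#' @param eta_hat,eta_true nonzero vectors of equal length.
#' @return error in degrees, clipped to `[0, 90]`.
#' @export
estimation_error <- function(eta_hat, eta_true) {
  a <- as.numeric(eta_hat); b <- as.numeric(eta_true)
  if (length(a) != length(b)) stop("vectors must have matching dimensions")
  max(0, min(90, angle_mod_sign(a, b) * 180 / pi))
}
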