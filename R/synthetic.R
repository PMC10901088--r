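# Synthetic inputs: leadfields with controlled spectra, ground-truth
# orientations, simulated sensor data, and analytic (population) covariances.

#' Simulation configuration
#'
#' Bundles all signal and noise parameters of one simulated recording: a
#' leadfield-normalized sinusoidal source of frequency `fq` sampled at `fs`
#' for `duration` seconds, plus per-channel i.i.d. Gaussian noise of standard
#' deviation `sigma` (or a modality-specific pair `sigma_e` / `sigma_m`).
#' The defaults -- a 20 Hz source, 600 Hz sampling, 60 s, hence
#' `T = 36000` samples and an integer 1200 source periods -- are the study
#' conditions all experiment drivers inherit.
#'
#' @param fq source frequency in Hz; must satisfy `fq < fs / 2`.
#' @param fs sampling rate in Hz.
#' @param duration record length in seconds.
#' @param sigma noise standard deviation (unitless, per channel per sample);
#'   used when a single noise level applies to all modalities.
#' @param sigma_e,sigma_m optional EEG / MEG noise levels for two-modality
#'   runs; either may be `NULL`, in which case `sigma` applies.
#' @param seed_noise,seed_orientation integer seeds for the noise stream and
#'   the ground-truth orientation stream.
#' @return an object of class `sim_config`; field `T` holds the sample count
#'   `round(fs * duration)`.
#' @export
sim_config <- function(fq = 20, fs = 600, duration = 60,
                       sigma = 1, sigma_e = NULL, sigma_m = NULL,
                       seed_noise = 1L, seed_orientation = 1L) {
  stopifnot(fq > 0, fs > 0, duration > 0)
  if (fq >= fs / 2) stop("source frequency must be below the Nyquist rate fs/2")
  for (s in c(sigma, sigma_e, sigma_m))
    if (!is.null(s) && (!is.finite(s) || s < 0)) stop("noise sd must be >= 0")
  structure(
    list(fq = fq, fs = fs, duration = duration,
         T = as.integer(round(fs * duration)),
         sigma = sigma, sigma_e = sigma_e, sigma_m = sigma_m,
         seed_noise = as.integer(seed_noise),
         seed_orientation = as.integer(seed_orientation)),
    class = "sim_config"
  )
}

#' Write / read a simulation configuration as flat JSON
#'
#' @param config a [sim_config].
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config]; `write_sim_config`
#'   returns `path` invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  jsonlite::write_json(unclass(config)[setdiff(names(config), "T")], path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  v <- jsonlite::fromJSON(path)
  do.call(sim_config, v[!vapply(v, is.null, logical(1))])
}

#' Generate a synthetic leadfield with a prescribed singular spectrum
#'
#' Draws seeded random orthonormal factors `U` (channels x 3) and `V`
#' (3 x 3) from QR decompositions of standard-Gaussian matrices and returns
#' `L = U diag(s) V'`.  The singular values of the output equal the request
#' to machine precision, so condition number and rank structure ("EEG-like"
#' full rank 3 versus "MEG-like" with a vanishing third value) are fully
#' controlled.
#'
#' @param n_channels number of sensor channels (at least 3).
#' @param singular_values decreasing nonnegative triple `(s1, s2, s3)` with
#'   `s1 > 0`.
#' @param seed integer seed; identical seeds give bit-identical matrices.
#' @param modality `"EEG"` (requires `s3 > 0`) or `"MEG"`.
#' @param label descriptive label.
#' @return a [leadfield].
#' @examples
#' L <- generate_synthetic_leadfield(60, c(1, 0.6, 0.1), seed = 7)
#' svd(L$matrix)$d
#' @export
generate_synthetic_leadfield <- function(n_channels, singular_values, seed,
                                         modality = c("EEG", "MEG"),
                                         label = "synthetic") {
  modality <- match.arg(modality)
  s <- as.numeric(singular_values)
  if (length(s) != 3L || any(!is.finite(s)) || any(s < 0))
    stop("singular_values must be three finite nonnegative numbers")
  if (is.unsorted(rev(s))) stop("singular values must be sorted decreasingly")
  if (s[1L] <= 0) stop("largest singular value must be positive")
  if (n_channels < 3L) stop("need at least 3 channels")
  with_seed(seed, {
    U <- haar_frame(n_channels, 3L)
    V <- haar_frame(3L, 3L)
    leadfield(U %*% (s * t(V)), modality = modality, label = label)
  })
}

# Orthonormal n x k factor from the QR decomposition of a Gaussian matrix,
# with the R-diagonal sign fixed so the draw is well defined.
haar_frame <- function(n, k) {
  G <- matrix(stats::rnorm(n * k), n, k)
  qr_ <- qr(G)
  Q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  d[d == 0] <- 1
  Q * rep(d, each = n)
}

#' Sample orientations uniformly on the unit sphere
#'
#' Normalized standard-Gaussian 3-vectors, the isotropic distribution of
#' ground-truth orientations used by the random-orientation experiment.
#'
#' @param n number of orientations (>= 1).
#' @param seed integer seed.
#' @return an `n` x 3 matrix of unit rows.
#' @export
sample_random_orientations <- function(n, seed) {
  if (n < 1) stop("n must be >= 1")
  with_seed(seed, {
    g <- matrix(stats::rnorm(3L * n), n, 3L)
    g / sqrt(rowSums(g^2))
  })
}

#' Convert target-frame spherical angles to a Cartesian orientation
#'
#' Azimuth is measured in the tangential plane from `vt1` toward `vt2`;
#' elevation is measured from the tangential plane toward the radial axis
#' `vr`:
#' `eta = cos(el) cos(az) vt1 + cos(el) sin(az) vt2 + sin(el) vr`.
#' Angles are in degrees and wrap freely.
#'
#' @param azimuth,elevation angles in degrees (vectors of equal length, or
#'   one of them scalar).
#' @param frame a [target_frame].
#' @return a unit 3-vector, or an n x 3 matrix of unit rows for vector input.
#' @export
spherical_to_cartesian <- function(azimuth, elevation, frame) {
  stopifnot(inherits(frame, "target_frame"))
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  n <- max(length(az), length(el))
  az <- rep_len(az, n); el <- rep_len(el, n)
  out <- outer(cos(el) * cos(az), frame$vt1) +
    outer(cos(el) * sin(az), frame$vt2) +
    outer(sin(el), frame$vr)
  if (n == 1L) drop(out) else out
}

#' Recover target-frame spherical angles from an orientation
#'
#' Inverse of [spherical_to_cartesian()] modulo the beamformer's sign
#' ambiguity: the vector is flipped, if needed, into the half-space with a
#' nonnegative `vt2` component, so the returned azimuth lies in `[0, 180]`
#' and elevation in `[-90, 90]`.
#'
#' @param v unit 3-vector.
#' @param frame a [target_frame].
#' @return named numeric vector `c(azimuth, elevation)` in degrees.
#' @export
cartesian_to_spherical <- function(v, frame) {
  stopifnot(inherits(frame, "target_frame"))
  a <- c(sum(frame$vt1 * v), sum(frame$vt2 * v), sum(frame$vr * v))
  a <- a / sqrt(sum(a^2))
  tol <- 1e-12   # treat a vanishing vt2 component as exactly zero
  if (a[2L] < -tol || (abs(a[2L]) <= tol && a[1L] < 0)) a <- -a
  if (abs(a[2L]) <= tol) a[2L] <- 0
  c(azimuth = atan2(a[2L], a[1L]) * 180 / pi,
    elevation = asin(max(-1, min(1, a[3L]))) * 180 / pi)
}

#' Build the fixed grid of scanned orientations
#'
#' Scans the sphere of possible source orientations in target-frame
#' spherical coordinates: azimuth over `[0, 180)` degrees and elevation over
#' `[-90, 90)` degrees, each in steps of `az_step` / `el_step`.  The upper
#' endpoints are dropped because azimuth 180 repeats azimuth 0 antipodally
#' and elevation 90 is the pole; with the default 9-degree steps this yields
#' exactly 20 x 20 = 400 orientations.
#'
#' @param frame a [target_frame].
#' @param az_step,el_step step sizes in degrees; must divide 180 evenly.
#' @return data frame with columns `azimuth`, `elevation`, `vx`, `vy`, `vz`
#'   (the unit orientation in sensor-frame Cartesian coordinates).
#' @export
make_orientation_grid <- function(frame, az_step = 9, el_step = 9) {
  stopifnot(inherits(frame, "target_frame"))
  if (az_step <= 0 || el_step <= 0 ||
      abs(180 / az_step - round(180 / az_step)) > 1e-9 ||
      abs(180 / el_step - round(180 / el_step)) > 1e-9)
    stop("step sizes must divide the 180-degree ranges evenly")
  az <- seq(0, 180 - az_step, by = az_step)
  el <- seq(-90, 90 - el_step, by = el_step)
  g <- expand.grid(azimuth = az, elevation = el, KEEP.OUT.ATTRS = FALSE)
  v <- spherical_to_cartesian(g$azimuth, g$elevation, frame)
  v <- base::as.matrix(v)
  data.frame(azimuth = g$azimuth, elevation = g$elevation,
             vx = v[, 1L], vy = v[, 2L], vz = v[, 3L])
}

#' Simulate sensor data for one source orientation
#'
#' The noise-free signal is the leadfield-normalized gain pattern times a
#' unit sinusoid, `dbar(t) = (L eta / ||L eta||) sin(2 pi fq t)`, sampled at
#' `fs` for `duration` seconds, so every source produces the same sensor
#' power (time-averaged 1/2 over the integer number of periods) regardless
#' of location or depth.  Temporally and spatially independent Gaussian
#' noise scaled to standard deviation `sigma` is added per channel and
#' sample: `d(t) = dbar(t) + sigma n(t)`.  `sigma` is therefore the
#' noise-to-signal scale of the recording.
#'
#' @param leadfield a [leadfield], or a bare gain matrix (channels x 3, or
#'   channels x 2 for a tangentially reduced MEG leadfield with a 2-vector
#'   orientation).
#' @param eta_sim ground-truth unit orientation (length matching the
#'   leadfield's column count).
#' @param config a [sim_config].
#' @param sigma optional noise level overriding the configuration (used by
#'   experiment drivers to bind `sigma_e` / `sigma_m`).
#' @return object of class `simulated_data`: list with `samples`
#'   (channels x T), `config`, `leadfield_label`, `eta_sim`, `sigma` and
#'   `seed_noise`.
#' @export
simulate_data <- function(leadfield, eta_sim, config = sim_config(), sigma = NULL) {
  stopifnot(inherits(config, "sim_config"))
  L <- if (inherits(leadfield, "leadfield")) leadfield$matrix
       else base::as.matrix(leadfield)
  label <- if (inherits(leadfield, "leadfield")) leadfield$label else "matrix"
  eta <- as.numeric(eta_sim)
  if (length(eta) != ncol(L)) stop("orientation length must match leadfield columns")
  if (abs(sqrt(sum(eta^2)) - 1) > 1e-12) eta <- unitize(eta)
  sigma <- sigma %||% config$sigma
  if (is.null(sigma) || sigma < 0) stop("noise sd must be >= 0")
  g <- drop(L %*% eta)
  ng <- sqrt(sum(g^2))
  if (ng <= 1e-12 * norm(L, "F"))
    stop("orientation lies in the leadfield null space (L eta = 0)")
  gbar <- g / ng
  tt <- (seq_len(config$T) - 1L) / config$fs
  s_t <- sin(2 * pi * config$fq * tt)
  samples <- tcrossprod(gbar, s_t)
  if (sigma > 0) {
    noise <- with_seed(config$seed_noise,
                       matrix(stats::rnorm(nrow(L) * config$T), nrow(L), config$T))
    samples <- samples + sigma * noise
  }
  structure(
    list(samples = samples, config = config, leadfield_label = label,
         eta_sim = eta, sigma = sigma, seed_noise = config$seed_noise),
    class = "simulated_data"
  )
}

#' Population second-moment matrix of the single-source model
#'
#' The exact covariance the sample second moment converges to: a rank-one
#' signal term plus the noise covariance,
#' `R = Q^2 x x' + sigma^2 I` for isotropic noise, or
#' `R = Q^2 x x' + N` for a general positive definite noise covariance `N`,
#' where `x` is the gain vector `L eta` (normalized or not).  With the
#' leadfield-normalized unit sinusoid of [simulate_data()], the source power
#' is `Q^2 = 1/2` (the time average of `sin^2` over whole periods), the
#' default.
#'
#' @param gain channel-space gain vector `L eta`.
#' @param source_power source power `Q^2` (> 0); defaults to 0.5.
#' @param sigma2 isotropic noise power `sigma^2` (>= 0); ignored when `N` is
#'   given.
#' @param N optional full noise covariance matrix (symmetric positive
#'   definite).
#' @return a `second_moment` object with `source = "analytic"`.
#' @export
analytic_covariance <- function(gain, source_power = 0.5, sigma2 = NULL, N = NULL) {
  x <- as.numeric(gain)
  if (!all(is.finite(x))) stop("non-finite gain vector")
  if (source_power <= 0) stop("source power must be positive")
  n <- length(x)
  if (is.null(N)) {
    if (is.null(sigma2) || sigma2 < 0) stop("sigma2 must be >= 0")
    noise <- diag(sigma2, n)
  } else {
    N <- base::as.matrix(N)
    ev <- eigen((N + t(N)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("noise covariance N must be positive definite")
    noise <- N
  }
  R <- source_power * tcrossprod(x) + noise
  new_second_moment((R + t(R)) / 2, source = "analytic", T_used = NA_integer_,
                    regularization_fraction = 0, regularized = FALSE)
}
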