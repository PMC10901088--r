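# Monte-Carlo experiment drivers: random-orientation error distributions,
# the EEG/MEG noise-level sweep, and the fixed-orientation bootstrap grid.

#' Configuration of a simulation experiment
#'
#' Collects the leadfields, methods, modalities, noise conditions, design
#' sizes and seeds of one experiment run.  Defaults reproduce the study
#' conditions: noise levels 0.5 / 2 / 4 with equal EEG and MEG noise, 1000
#' random orientations, a 9-degree orientation grid with 100 bootstrap
#' replicates, 5 percent covariance regularization, and a 20 Hz source
#' sampled at 600 Hz for 60 s.
#'
#' @param eeg_leadfield,meg_leadfield [leadfield] objects (either may be
#'   omitted when no modality requires it).
#' @param frame optional [target_frame]; derived from `meg_leadfield` when
#'   missing.
#' @param methods subset of `c("UG", "UNG", "AG")`.
#' @param modalities subset of `c("MEG", "EEG", "EMEG")`; `EMEG` needs both
#'   leadfields.
#' @param sigma_list noise levels for the random-orientation and grid
#'   experiments (applied as `sigma_e = sigma_m = sigma`).
#' @param sigma_e_list,sigma_m EEG noise levels and the fixed MEG noise
#'   level of the noise sweep.
#' @param n_orientations random orientations per condition.
#' @param az_step,el_step grid steps in degrees.
#' @param bootstrap_count bootstrap replicates per grid orientation.
#' @param regularization_fraction diagonal-loading fraction for all sample
#'   covariances.
#' @param fq,fs,duration source frequency, sampling rate and record length.
#' @param seed_orientation,seed_noise,seed_bootstrap independent seeds for
#'   the three stochastic stages, all recorded in the outputs.
#' @param label target label for the result tables.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(eeg_leadfield = NULL, meg_leadfield = NULL,
                              frame = NULL,
                              methods = c("UG", "UNG", "AG"),
                              modalities = c("MEG", "EEG", "EMEG"),
                              sigma_list = c(0.5, 2, 4),
                              sigma_e_list = seq(0.5, 10, by = 0.5),
                              sigma_m = 4,
                              n_orientations = 1000L,
                              az_step = 9, el_step = 9,
                              bootstrap_count = 100L,
                              regularization_fraction = 0.05,
                              fq = 20, fs = 600, duration = 60,
                              seed_orientation = 101L,
                              seed_noise = 202L,
                              seed_bootstrap = 303L,
                              label = NULL) {
  methods <- match.arg(methods, c("UG", "UNG", "AG"), several.ok = TRUE)
  modalities <- match.arg(modalities, c("MEG", "EEG", "EMEG"), several.ok = TRUE)
  if (any(c("EEG", "EMEG") %in% modalities) && is.null(eeg_leadfield))
    stop("EEG / EMEG modalities require an EEG leadfield")
  if (any(c("MEG", "EMEG") %in% modalities) && is.null(meg_leadfield) && is.null(frame))
    stop("MEG / EMEG modalities require an MEG leadfield (or a frame)")
  if (is.null(frame) && !is.null(meg_leadfield))
    frame <- make_target_frame(meg_leadfield)
  stopifnot(all(sigma_list >= 0), all(sigma_e_list >= 0), sigma_m >= 0,
            n_orientations >= 1, bootstrap_count >= 1,
            regularization_fraction >= 0)
  if (is.null(label)) {
    label <- if (!is.null(eeg_leadfield)) eeg_leadfield$label
             else if (!is.null(meg_leadfield)) meg_leadfield$label
             else "unlabeled"
  }
  structure(
    list(eeg_leadfield = eeg_leadfield, meg_leadfield = meg_leadfield,
         frame = frame, methods = methods, modalities = modalities,
         sigma_list = sigma_list, sigma_e_list = sigma_e_list,
         sigma_m = sigma_m,
         n_orientations = as.integer(n_orientations),
         az_step = az_step, el_step = el_step,
         bootstrap_count = as.integer(bootstrap_count),
         regularization_fraction = regularization_fraction,
         fq = fq, fs = fs, duration = duration,
         seed_orientation = as.integer(seed_orientation),
         seed_noise = as.integer(seed_noise),
         seed_bootstrap = as.integer(seed_bootstrap),
         label = label),
    class = "experiment_config"
  )
}

# One record row.  epsilon is NA when the trial was skipped.
error_record <- function(cfg, method, modality, sigma_e, sigma_m,
                         orientation_id, epsilon, degenerate, skipped,
                         seed_noise, azimuth = NA_real_, elevation = NA_real_,
                         replicate = NA_integer_) {
  data.frame(target = cfg$label, method = method, modality = modality,
             sigma_e = sigma_e, sigma_m = sigma_m,
             orientation_id = orientation_id,
             azimuth = azimuth, elevation = elevation,
             replicate = replicate, epsilon = epsilon,
             degenerate = degenerate, skipped = skipped,
             seed_noise = seed_noise, stringsAsFactors = FALSE)
}

# Per-method orientation estimates from precomputed covariances for one
# trial; returns the record rows for all requested modalities.
trial_records <- function(cfg, eta, sigma_e, sigma_m, orientation_id,
                          seed_e, seed_m, azimuth = NA_real_,
                          elevation = NA_real_, replicate = NA_integer_,
                          R_e = NULL, R_m = NULL) {
  need_eeg <- any(c("EEG", "EMEG") %in% cfg$modalities)
  need_meg <- any(c("MEG", "EMEG") %in% cfg$modalities)
  rows <- list()
  est_e <- est_m <- NULL
  if (need_eeg) {
    if (is.null(R_e)) {
      sc <- sim_config(fq = cfg$fq, fs = cfg$fs, duration = cfg$duration,
                       sigma = sigma_e, seed_noise = seed_e)
      R_e <- estimate_covariance(simulate_data(cfg$eeg_leadfield, eta, sc),
                                 cfg$regularization_fraction)
    }
    est_e <- lapply(cfg$methods, function(m)
      estimate_orientation(cfg$eeg_leadfield, R_e, m, modality = "EEG"))
    names(est_e) <- cfg$methods
  }
  et_true <- NULL
  if (need_meg) {
    et_true <- tangential_component(cfg$frame, eta)
    if (is.null(R_m)) {
      sc <- sim_config(fq = cfg$fq, fs = cfg$fs, duration = cfg$duration,
                       sigma = sigma_m, seed_noise = seed_m)
      meg_lf <- cfg$meg_leadfield
      R_m <- tryCatch(
        estimate_covariance(simulate_data(meg_lf, eta, sc),
                            cfg$regularization_fraction),
        error = function(e) NULL)   # eta in the MEG null space
    }
    if (!is.null(R_m)) {
      est_m <- lapply(cfg$methods, function(m)
        estimate_orientation(cfg$frame$reduced_meg, R_m, m, modality = "MEG"))
      names(est_m) <- cfg$methods
    }
  }
  for (m in cfg$methods) {
    if ("EEG" %in% cfg$modalities) {
      rows[[length(rows) + 1L]] <- error_record(
        cfg, m, "EEG", sigma_e, sigma_m, orientation_id,
        estimation_error(est_e[[m]]$eta_hat, eta),
        est_e[[m]]$degenerate, FALSE, seed_e, azimuth, elevation, replicate)
    }
    if ("MEG" %in% cfg$modalities) {
      skip <- is.null(est_m) || sqrt(sum(et_true^2)) < 1e-12
      rows[[length(rows) + 1L]] <- error_record(
        cfg, m, "MEG", sigma_e, sigma_m, orientation_id,
        if (skip) NA_real_ else estimation_error(est_m[[m]]$eta_hat, et_true),
        if (skip) FALSE else est_m[[m]]$degenerate, skip, seed_m,
        azimuth, elevation, replicate)
    }
    if ("EMEG" %in% cfg$modalities) {
      skip <- is.null(est_m)
      eps <- NA_real_
      degen <- FALSE
      if (!skip) {
        fused <- fuse_emeg(est_m[[m]]$eta_hat, est_e[[m]]$eta_hat, cfg$frame)
        eps <- estimation_error(fused, eta)
        degen <- est_e[[m]]$degenerate || est_m[[m]]$degenerate
      }
      rows[[length(rows) + 1L]] <- error_record(
        cfg, m, "EMEG", sigma_e, sigma_m, orientation_id, eps, degen, skip,
        seed_e, azimuth, elevation, replicate)
    }
  }
  do.call(rbind, rows)
}

#' Summary statistic of a set of estimation errors with a confidence interval
#'
#' The mean with a normal-approximation interval
#' `mean +/- z * sd / sqrt(n)`, or the median with a percentile-bootstrap
#' interval.
#'
#' @param records numeric vector of errors in degrees, or a data frame with
#'   an `epsilon` column (rows flagged `skipped` or `degenerate` are
#'   excluded).
#' @param statistic `"mean"` or `"median"`.
#' @param ci_level confidence level (default 0.95).
#' @param n_boot bootstrap replicates for the median interval.
#' @param seed seed for the bootstrap interval.
#' @return one-row data frame: `statistic`, `value`, `ci_lo`, `ci_hi`, `n`.
#' @export
summarize_errors <- function(records, statistic = c("mean", "median"),
                             ci_level = 0.95, n_boot = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  x <- if (is.data.frame(records)) {
    keep <- !(records$skipped %||% FALSE) & !(records$degenerate %||% FALSE)
    records$epsilon[keep]
  } else as.numeric(records)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) stop("no usable error records")
  if (statistic == "mean") {
    v <- mean(x)
    if (n >= 2L) {
      half <- stats::qnorm(1 - (1 - ci_level) / 2) * stats::sd(x) / sqrt(n)
      ci <- c(v - half, v + half)
    } else ci <- c(NA_real_, NA_real_)
  } else {
    v <- stats::median(x)
    ci <- if (n >= 2L) {
      meds <- with_seed(seed, vapply(seq_len(n_boot), function(i)
        stats::median(x[sample.int(n, n, replace = TRUE)]), numeric(1)))
      unname(stats::quantile(meds, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)))
    } else c(NA_real_, NA_real_)
  }
  data.frame(statistic = statistic, value = v, ci_lo = ci[1L], ci_hi = ci[2L],
             n = n)
}

# Group-wise summary table over (sigma_e, sigma_m, method, modality
# [, orientation]) with degenerate/skipped bookkeeping.
summarize_records <- function(records, statistic = "mean", ci_level = 0.95,
                              by_orientation = FALSE) {
  keys <- c("target", "sigma_e", "sigma_m", "method", "modality")
  if (by_orientation) keys <- c(keys, "orientation_id", "azimuth", "elevation")
  grp <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  out <- lapply(split(records, grp), function(r) {
    usable <- r[!r$skipped & !r$degenerate & is.finite(r$epsilon), , drop = FALSE]
    s <- if (nrow(usable)) summarize_errors(usable$epsilon, statistic, ci_level)
         else data.frame(statistic = statistic, value = NA_real_,
                         ci_lo = NA_real_, ci_hi = NA_real_, n = 0L)
    cbind(r[1L, keys, drop = FALSE], s,
          n_degenerate = sum(r$degenerate, na.rm = TRUE),
          n_skipped = sum(r$skipped, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Random-orientation experiment: error distributions per noise level
#'
#' For each noise level in `sigma_list`, draws fresh uniform ground-truth
#' orientations, simulates one EEG and/or MEG dataset per orientation with
#' fresh noise (`sigma_e = sigma_m = sigma`), estimates the orientation with
#' every configured method and modality on the regularized sample
#' covariance (MEG in the tangential plane, EMEG by fusion), and scores the
#' angular error against the ground truth.
#'
#' @param config an [experiment_config].
#' @return object of class `experiment_result`: list with `records` (one
#'   row per trial), `summary` (mean and 95 percent interval per
#'   condition), and `config`.
#' @export
run_random_orientation_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_orientations
  all_rows <- vector("list", length(config$sigma_list))
  for (ci in seq_along(config$sigma_list)) {
    sig <- config$sigma_list[ci]
    etas <- sample_random_orientations(n, config$seed_orientation + ci - 1L)
    seeds <- derive_seeds(config$seed_noise + ci - 1L, 2L * n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- trial_records(config, etas[i, ], sig, sig, i,
                                 seeds[2L * i - 1L], seeds[2L * i])
    }
    all_rows[[ci]] <- do.call(rbind, rows)
  }
  records <- do.call(rbind, all_rows)
  structure(list(records = records,
                 summary = summarize_records(records, "mean"),
                 config = config),
            class = "experiment_result")
}

#' Noise sweep: EEG versus combined EEG-MEG across EEG noise levels
#'
#' Holds the MEG noise level fixed at `sigma_m` and sweeps the EEG noise
#' level over `sigma_e_list`, repeating the random-orientation experiment
#' at each setting.  The summary exposes, per EEG noise level and method,
#' the mean error of the EEG and fused EMEG estimates (and of the MEG
#' reference when configured), which exhibits the crossover: EEG wins while
#' `sigma_e < sigma_m`, the fusion wins beyond.
#'
#' @param config an [experiment_config].
#' @return an `experiment_result` (one summary row per
#'   `sigma_e` x method x modality).
#' @export
run_noise_sweep <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  n <- config$n_orientations
  all_rows <- vector("list", length(config$sigma_e_list))
  for (ci in seq_along(config$sigma_e_list)) {
    sig_e <- config$sigma_e_list[ci]
    etas <- sample_random_orientations(n, config$seed_orientation + ci - 1L)
    seeds <- derive_seeds(config$seed_noise + ci - 1L, 2L * n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      rows[[i]] <- trial_records(config, etas[i, ], sig_e, config$sigma_m, i,
                                 seeds[2L * i - 1L], seeds[2L * i])
    }
    all_rows[[ci]] <- do.call(rbind, rows)
  }
  records <- do.call(rbind, all_rows)
  structure(list(records = records,
                 summary = summarize_records(records, "mean"),
                 config = config),
            class = "experiment_result")
}

# Weighted bootstrap second moment: resampling T columns with replacement is
# equivalent to multinomial weights on the outer products.
bootstrap_covariance <- function(X, regularization_fraction) {
  T_used <- ncol(X)
  cnt <- tabulate(sample.int(T_used, T_used, replace = TRUE), T_used)
  R <- (X * rep(cnt, each = nrow(X))) %*% t(X) / T_used
  R <- (R + t(R)) / 2
  if (regularization_fraction > 0)
    R <- R + diag(regularization_fraction * sum(diag(R)) / nrow(R), nrow(R))
  new_second_moment(R, source = "sample", T_used = T_used,
                    regularization_fraction = regularization_fraction,
                    regularized = regularization_fraction > 0)
}

#' Bootstrap-resampled orientation errors for one simulated dataset
#'
#' Draws `B` resamples of the time samples of one simulated record (with
#' replacement, each of the full record length), estimates the source
#' orientation on each resampled, regularized covariance, and returns the
#' angular error of every replicate against the ground truth.  The median
#' of the returned errors is the per-orientation statistic of the
#' fixed-orientation experiment.
#'
#' @param samples a `simulated_data` object or channels x T matrix.
#' @param leadfield leadfield (or reduced leadfield matrix) to estimate
#'   with.
#' @param eta_true ground-truth orientation matching the leadfield's
#'   column count.
#' @param B number of bootstrap replicates.
#' @param method `"UG"`, `"UNG"` or `"AG"`.
#' @param regularization_fraction diagonal-loading fraction.
#' @param seed seed for the resampling.
#' @return numeric vector of `B` errors in degrees.
#' @export
bootstrap_orientation_errors <- function(samples, leadfield, eta_true,
                                         B = 100L, method = "UG",
                                         regularization_fraction = 0.05,
                                         seed = 1L) {
  X <- if (inherits(samples, "simulated_data")) samples$samples
       else base::as.matrix(samples)
  with_seed(seed, vapply(seq_len(B), function(b) {
    R <- bootstrap_covariance(X, regularization_fraction)
    estimation_error(estimate_orientation(leadfield, R, method)$eta_hat,
                     eta_true)
  }, numeric(1)))
}

#' Fixed-orientation grid experiment with bootstrap resampling
#'
#' Scans the grid of [make_orientation_grid()].  For every grid orientation
#' and noise level, one full dataset is simulated; the orientation is then
#' re-estimated on `bootstrap_count` covariances built from resamples of
#' the time samples (drawn with replacement, each of the full record
#' length), and the median of the replicate errors is reported per method
#' and modality, keyed by the grid angles for map output.
#'
#' @param config an [experiment_config].
#' @return an `experiment_result`; `records` holds one row per bootstrap
#'   replicate, `summary` the per-orientation medians.
#' @export
run_fixed_orientation_grid <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(config$frame))
    stop("grid experiment requires a target frame (MEG leadfield)")
  grid <- make_orientation_grid(config$frame, config$az_step, config$el_step)
  need_eeg <- any(c("EEG", "EMEG") %in% config$modalities)
  need_meg <- any(c("MEG", "EMEG") %in% config$modalities)
  B <- config$bootstrap_count
  all_rows <- list()
  for (ci in seq_along(config$sigma_list)) {
    sig <- config$sigma_list[ci]
    seeds <- derive_seeds(config$seed_noise + ci - 1L, 2L * nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      eta <- c(grid$vx[gi], grid$vy[gi], grid$vz[gi])
      X_e <- X_m <- NULL
      if (need_eeg) {
        sc <- sim_config(fq = config$fq, fs = config$fs,
                         duration = config$duration, sigma = sig,
                         seed_noise = seeds[2L * gi - 1L])
        X_e <- simulate_data(config$eeg_leadfield, eta, sc)$samples
      }
      if (need_meg) {
        sc <- sim_config(fq = config$fq, fs = config$fs,
                         duration = config$duration, sigma = sig,
                         seed_noise = seeds[2L * gi])
        X_m <- tryCatch(simulate_data(config$meg_leadfield, eta, sc)$samples,
                        error = function(e) NULL)
      }
      rows <- with_seed(config$seed_bootstrap + 7919L * (ci - 1L) + gi, {
        reps <- vector("list", B)
        for (b in seq_len(B)) {
          R_e <- if (!is.null(X_e))
            bootstrap_covariance(X_e, config$regularization_fraction)
          R_m <- if (!is.null(X_m))
            bootstrap_covariance(X_m, config$regularization_fraction)
          reps[[b]] <- trial_records(
            config, eta, sig, sig, gi,
            seeds[2L * gi - 1L], seeds[2L * gi],
            azimuth = grid$azimuth[gi], elevation = grid$elevation[gi],
            replicate = b, R_e = R_e, R_m = R_m)
        }
        do.call(rbind, reps)
      })
      all_rows[[length(all_rows) + 1L]] <- rows
    }
  }
  records <- do.call(rbind, all_rows)
  structure(list(records = records,
                 summary = summarize_records(records, "median",
                                             by_orientation = TRUE),
                 config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d records, %d summary rows, target '%s'\n",
              nrow(x$records), nrow(x$summary), x$config$label))
  invisible(x)
}

#' Correlate per-target errors with a leadfield property
#'
#' Pearson correlation (with the two-sided t-test p value, uncorrected)
#' between per-target summary errors and a per-target leadfield property
#' such as the condition number or the source depth.
#'
#' @param errors numeric vector of per-target errors (e.g. median error).
#' @param property numeric vector of the same length (e.g. condition
#'   numbers).
#' @return list with `r`, `p`, and `n`.
#' @export
correlate_errors_with_leadfield_property <- function(errors, property) {
  errors <- as.numeric(errors); property <- as.numeric(property)
  if (length(errors) != length(property)) stop("paired vectors required")
  if (length(errors) < 3L) stop("need at least 3 paired values")
  if (stats::var(errors) == 0 || stats::var(property) == 0)
    stop("zero variance in one of the inputs; correlation undefined")
  ct <- stats::cor.test(property, errors, method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(errors))
}
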