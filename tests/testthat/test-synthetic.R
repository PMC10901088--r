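# Synthetic leadfields, orientations, simulated data and analytic covariance.

test_that("simulation config enforces its invariants and serializes", {
  sc <- sim_config()
  expect_identical(sc$T, 36000L)
  expect_identical(sc$fs * sc$duration, 36000)
  # integer samples per source period under the defaults
  expect_equal(sc$fs / sc$fq, 30)
  expect_error(sim_config(fq = 400, fs = 600), "Nyquist")
  expect_error(sim_config(sigma = -1), ">= 0")

  path <- withr::local_tempfile(fileext = ".json")
  write_sim_config(sim_config(sigma = 2.5, duration = 10, seed_noise = 77),
                   path)
  back <- read_sim_config(path)
  expect_equal(back$sigma, 2.5)
  expect_identical(back$T, 6000L)
  expect_identical(back$seed_noise, 77L)
})

test_that("synthetic leadfields carry the requested singular spectrum", {
  lf <- generate_synthetic_leadfield(50, c(3, 2, 1), seed = 8)
  expect_equal(svd(lf$matrix)$d, c(3, 2, 1), tolerance = 1e-10)

  # rank-2 MEG-like request
  lf2 <- generate_synthetic_leadfield(50, c(3, 2, 0), seed = 8,
                                      modality = "MEG")
  s <- svd(lf2$matrix)$d
  expect_equal(s[1:2], c(3, 2), tolerance = 1e-10)
  expect_lt(s[3], 1e-12)

  # determinism contract
  expect_identical(generate_synthetic_leadfield(20, c(1, 0.5, 0.1), seed = 3)$matrix,
                   generate_synthetic_leadfield(20, c(1, 0.5, 0.1), seed = 3)$matrix)
  expect_false(identical(
    generate_synthetic_leadfield(20, c(1, 0.5, 0.1), seed = 3)$matrix,
    generate_synthetic_leadfield(20, c(1, 0.5, 0.1), seed = 4)$matrix))

  expect_error(generate_synthetic_leadfield(50, c(1, 2, 3), seed = 1),
               "sorted")
  expect_error(generate_synthetic_leadfield(2, c(3, 2, 1), seed = 1),
               "channels")
})

test_that("random orientations are unit, isotropic and seed-reproducible", {
  E <- sample_random_orientations(1e5, seed = 42)
  expect_lt(max(abs(sqrt(rowSums(E^2)) - 1)), 1e-12)
  # E|cos(theta)| = 1/2 on the uniform sphere
  expect_gt(mean(abs(E[, 3])), 0.49)
  expect_lt(mean(abs(E[, 3])), 0.51)
  # each component mean near zero
  expect_true(all(abs(colMeans(E)) < 0.01))
  expect_identical(E, sample_random_orientations(1e5, seed = 42))
  expect_error(sample_random_orientations(0, seed = 1), ">= 1")
})

test_that("spherical coordinates follow the tangential/radial convention", {
  fr <- make_target_frame(
    generate_synthetic_leadfield(20, c(1, 0.6, 0.1), seed = 2,
                                 modality = "MEG"))
  expect_equal(spherical_to_cartesian(0, 0, fr), fr$vt1, tolerance = 1e-12)
  expect_equal(spherical_to_cartesian(90, 0, fr), fr$vt2, tolerance = 1e-12)
  expect_equal(spherical_to_cartesian(33, 90, fr), fr$vr, tolerance = 1e-12)
  rt <- cartesian_to_spherical(spherical_to_cartesian(27, -36, fr), fr)
  expect_equal(unname(rt), c(27, -36), tolerance = 1e-9)
})

test_that("the default orientation grid has 400 unit entries", {
  fr <- make_target_frame(
    generate_synthetic_leadfield(24, c(1, 0.7, 0.2), seed = 13,
                                 modality = "MEG"))
  g <- make_orientation_grid(fr)
  expect_identical(nrow(g), 400L)
  expect_identical(length(unique(g$azimuth)), 20L)
  expect_identical(length(unique(g$elevation)), 20L)
  V <- as.matrix(g[, c("vx", "vy", "vz")])
  expect_lt(max(abs(sqrt(rowSums(V^2)) - 1)), 1e-12)
  # first entry (az 0, el 0 is on the grid) equals vt1
  i0 <- which(g$azimuth == 0 & g$elevation == 0)
  expect_equal(unname(V[i0, ]), fr$vt1, tolerance = 1e-12)
  # angles round-trip away from the elevation pole
  off_pole <- which(g$elevation > -90)
  for (i in off_pole[seq(1, length(off_pole), by = 37)]) {
    rt <- cartesian_to_spherical(V[i, ], fr)
    expect_equal(unname(rt), c(g$azimuth[i], g$elevation[i]),
                 tolerance = 1e-9)
  }
  # off the pole, no two grid orientations are collinear
  G <- abs(V[off_pole, ] %*% t(V[off_pole, ]))
  diag(G) <- 0
  expect_lt(max(G), 1 - 1e-9)
  expect_error(make_orientation_grid(fr, az_step = 7), "divide")
})

test_that("noise-free simulated data is the normalized gain times a sinusoid", {
  lf <- generate_synthetic_leadfield(16, c(1, 0.6, 0.1), seed = 31)
  eta <- drop(sample_random_orientations(1, 7))
  sc <- sim_config(sigma = 0, duration = 2)
  sim <- simulate_data(lf, eta, sc)
  expect_identical(ncol(sim$samples), 1200L)
  g <- drop(lf$matrix %*% eta)
  gbar <- g / sqrt(sum(g^2))
  tt <- (0:1199) / 600
  expect_equal(sim$samples, tcrossprod(gbar, sin(2 * pi * 20 * tt)),
               tolerance = 1e-15)
  # time-averaged sensor power is exactly 1/2 over whole periods
  expect_equal(mean(colSums(sim$samples^2)), 0.5, tolerance = 1e-12)
})

test_that("simulated record length and noise scale match the configuration", {
  lf <- generate_synthetic_leadfield(8, c(1, 0.6, 0.1), seed = 3)
  eta <- c(1, 0, 0)
  sim <- simulate_data(lf, eta, sim_config(sigma = 2, seed_noise = 9))
  expect_identical(ncol(sim$samples), 36000L)
  # isolate the noise by subtracting the deterministic signal part
  clean <- simulate_data(lf, eta, sim_config(sigma = 0))
  noise <- sim$samples - clean$samples
  v <- apply(noise, 1, var)
  expect_true(all(v > 3.9 & v < 4.1))
  # same noise seed reproduces the record
  sim2 <- simulate_data(lf, eta, sim_config(sigma = 2, seed_noise = 9))
  expect_identical(sim$samples, sim2$samples)
})

test_that("orientations in the leadfield null space are rejected", {
  lf <- generate_synthetic_leadfield(12, c(1, 0.5, 0), seed = 6,
                                     modality = "MEG")
  fr <- make_target_frame(lf)
  expect_error(simulate_data(lf, fr$vr, sim_config(sigma = 1, duration = 1)),
               "null space")
})

test_that("analytic covariance has the rank-one-update spectrum", {
  set.seed(5)
  g <- rnorm(10); g <- g / sqrt(sum(g^2))
  R <- analytic_covariance(g, source_power = 0.5, sigma2 = 4)
  ev <- eigen(R$R, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1], 4.5, tolerance = 1e-12)
  expect_equal(ev[-1], rep(4, 9), tolerance = 1e-12)

  x <- rnorm(6)
  R0 <- analytic_covariance(x, source_power = 1, sigma2 = 0)
  expect_equal(qr(R0$R)$rank, 1L)

  N <- diag(1:6)
  Rg <- analytic_covariance(x, source_power = 2, N = N)
  D <- Rg$R - N
  expect_equal(qr(D)$rank, 1L)
  expect_equal(sum(diag(D)), 2 * sum(x^2), tolerance = 1e-12)
  expect_error(analytic_covariance(x, 1, N = diag(c(1, 1, 1, 1, 1, -1))),
               "positive definite")
})

test_that("sample second moment converges to the analytic covariance", {
  lf <- generate_synthetic_leadfield(20, c(1, 0.6, 0.1), seed = 17)
  eta <- drop(sample_random_orientations(1, 18))
  sim <- simulate_data(lf, eta, sim_config(sigma = 1, seed_noise = 19))
  Rs <- estimate_covariance(sim, regularization_fraction = 0)
  Ra <- analytic_covariance(drop(lf$matrix %*% eta) /
                              sqrt(sum((lf$matrix %*% eta)^2)),
                            source_power = 0.5, sigma2 = 1)
  rel <- norm(Rs$R - Ra$R, "F") / norm(Ra$R, "F")
  expect_lt(rel, 0.05)
})
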