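# Closed-form reconstruction theory: UG limits, secular equation, scores.

test_that("high-noise UG limit is the weakest singular direction", {
  expect_equal(ug_high_noise_limit(diag(c(3, 2, 1))), c(0, 0, 1),
               tolerance = 1e-12)
  for (seed in 1:5) {
    lf <- generate_synthetic_leadfield(24, c(1, 0.6, 0.1), seed = seed)
    # SVD cross-check: smallest right singular vector
    v3 <- svd(lf$matrix)$v[, 3]
    expect_lt(angle_to(ug_high_noise_limit(lf), v3), 1e-10)
  }
  # degenerate smallest eigenvalue is refused
  expect_error(ug_high_noise_limit(diag(c(2, 1, 1))), "degenerate")
})

test_that("high-noise UG limit honors a general noise shape", {
  set.seed(61)
  L <- matrix(rnorm(30), 10, 3)
  N0 <- random_pd(10)
  v <- ug_high_noise_limit(L, N0)
  A <- t(L) %*% solve(N0, L)
  oracle <- eigen((A + t(A)) / 2, symmetric = TRUE)$vectors[, 3]
  expect_lt(angle_to(v, oracle), 1e-10)
})

test_that("UG estimator approaches both closed-form limits", {
  for (seed in 1:5) {
    cs <- fixture_case(seed)
    R_hi <- analytic_covariance(cs$x, 0.5, sigma2 = 1e12)
    est_hi <- estimate_orientation(cs$lf$matrix, R_hi, "UG")
    expect_lt(angle_to(est_hi$eta_hat, ug_high_noise_limit(cs$lf$matrix)),
              1e-3)
    # EEG low noise: the truth itself
    R_lo <- analytic_covariance(cs$x, 0.5, sigma2 = 1e-12)
    est_lo <- estimate_orientation(cs$lf$matrix, R_lo, "UG")
    expect_lt(angle_to(est_lo$eta_hat, cs$eta), 1e-4)
  }
})

test_that("secular root is exact for purely tangential sources", {
  s1 <- 2; s2 <- 1; et <- c(0.6, 0.8)
  rhs <- (s1 * et[1])^2 + (s2 * et[2])^2   # ||LMred eta_t||^2
  lam <- solve_secular(s1, s2, et, rhs)
  expect_equal(as.numeric(lam), 0, tolerance = 1e-10)
  # the reported gap is the pole distance s2^2 - lambda
  expect_equal(attr(lam, "gap"), s2^2 - as.numeric(lam), tolerance = 1e-12)
})

test_that("secular roots satisfy the equation on back-substitution", {
  s1 <- 2; s2 <- 1; et <- c(0.6, 0.8)
  f <- function(lam) (s1^2 * et[1])^2 / (s1^2 - lam) +
    (s2^2 * et[2])^2 / (s2^2 - lam)
  set.seed(71)
  for (rhs in runif(20, 0.05, 50)) {
    lam <- as.numeric(solve_secular(s1, s2, et, rhs))
    expect_lt(lam, s2^2)
    expect_lt(abs(f(lam) - rhs), 1e-10 * max(1, rhs))
  }
})

test_that("secular root increases strictly with the right-hand side", {
  set.seed(72)
  for (i in 1:100) {
    s1 <- runif(1, 1, 3)
    s2 <- runif(1, 0.2, s1)
    et <- rnorm(2); et <- et / sqrt(sum(et^2))
    if (min(abs(et)) < 1e-3) next
    rhs <- sort(runif(2, 0.05, 20))
    l1 <- as.numeric(solve_secular(s1, s2, et, rhs[1]))
    l2 <- as.numeric(solve_secular(s1, s2, et, rhs[2]))
    expect_lt(l1, l2)
  }
})

test_that("MEG low-noise limit collapses to the tangential truth when radial content vanishes", {
  # s3 = 0: no radial leadfield
  lf <- generate_synthetic_leadfield(20, c(1, 0.5, 0), seed = 81,
                                     modality = "MEG")
  fr <- make_target_frame(lf)
  eta <- drop(sample_random_orientations(1, 82))
  et <- tangential_of(fr, eta)
  expect_lt(angle_to(meg_low_noise_limit(fr, eta), et), 1e-9)

  # purely tangential truth with s3 > 0
  cs <- fixture_case(83)
  eta_t <- cos(1.1) * cs$frame$vt1 + sin(1.1) * cs$frame$vt2
  expect_lt(angle_to(meg_low_noise_limit(cs$frame, eta_t),
                     tangential_of(cs$frame, eta_t)), 1e-9)

  # purely radial truth is refused
  expect_error(meg_low_noise_limit(cs$frame, cs$frame$vr), "radial")
})

test_that("MEG low-noise limit matches the estimator and differs from the tangential truth", {
  for (seed in 1:5) {
    cs <- fixture_case(seed, sv = c(1, 0.6, 0.3))
    R <- analytic_covariance(cs$x, 0.5, sigma2 = 1e-12)
    est <- estimate_orientation(cs$frame$reduced_meg, R, "UG")
    tl <- meg_low_noise_limit(cs$frame, cs$eta)
    expect_lt(angle_to(est$eta_hat, tl), 1e-4)
  }
  # with a strong radial leadfield component and radial truth content the
  # limit is measurably different from the normalized tangential component
  cs <- fixture_case(91, sv = c(1, 0.6, 0.3))
  eta <- unit(0.5 * cs$frame$vt1 + 0.3 * cs$frame$vt2 + 0.8 * cs$frame$vr)
  tl <- meg_low_noise_limit(cs$frame, eta)
  expect_gt(angle_to(tl, tangential_of(cs$frame, eta)), 1e-3)
})

test_that("degenerate tangential spectrum is refused by the closed forms", {
  lf <- generate_synthetic_leadfield(20, c(1, 1, 0.2), seed = 84,
                                     modality = "MEG")
  fr <- make_target_frame(lf)
  expect_error(meg_low_noise_limit(fr, c(1, 0, 0)), "degenerate")
})

test_that("finite-noise closed form is continuous at zero and reaches the high-noise axis", {
  cs <- fixture_case(85, sv = c(1, 0.6, 0.2))
  lo <- meg_low_noise_limit(cs$frame, cs$eta)
  near0 <- expected_ug_finite_noise(cs$frame, cs$eta, 0.5, 1e-14)
  expect_lt(angle_to(near0, lo), 1e-8)
  hi <- expected_ug_finite_noise(cs$frame, cs$eta, 0.5, 1e8)
  expect_lt(angle_to(hi, c(0, 1)), 1e-3)
})

test_that("finite-noise closed form agrees with the eigen solver", {
  for (seed in 1:10) {
    cs <- fixture_case(seed + 100)
    for (sigma2 in c(0.25, 4, 100)) {
      R <- analytic_covariance(cs$x, 0.5, sigma2 = sigma2)
      est <- estimate_orientation(cs$frame$reduced_meg, R, "UG")
      cf <- expected_ug_finite_noise(cs$frame, cs$eta, 0.5, sigma2)
      expect_lt(angle_to(est$eta_hat, cf), 1e-6)
    }
  }
})

test_that("expected estimates depend on the leadfield only through its spectrum", {
  # channel-space rotation leaves the closed-form expectation unchanged
  cs <- fixture_case(111, n_channels = 18L)
  set.seed(112)
  Q <- qr.Q(qr(matrix(rnorm(18 * 18), 18)))
  fr_rot <- make_target_frame(leadfield(Q %*% cs$lf$matrix, "MEG"))
  a <- expected_ug_finite_noise(cs$frame, cs$eta, 0.5, 4)
  b <- expected_ug_finite_noise(fr_rot, cs$eta, 0.5, 4)
  expect_lt(angle_to(a, b), 1e-8)
})

test_that("larger condition numbers pull the expected UG estimate to the weak axis faster", {
  # fixed tangential truth mixture, fixed noise; tangential condition
  # number s1/s2 swept upward
  angles <- vapply(c(2, 5, 10, 50), function(k) {
    lf <- generate_synthetic_leadfield(30, c(1, 1 / k, 1 / (4 * k)),
                                       seed = 120, modality = "MEG")
    fr <- make_target_frame(lf)
    eta <- unit(0.8 * fr$vt1 + 0.55 * fr$vt2 + 0.24 * fr$vr)
    cf <- expected_ug_finite_noise(fr, eta, 0.5, 4)
    angle_to(cf, c(0, 1))
  }, numeric(1))
  expect_true(all(diff(angles) <= 1e-12))
})

test_that("pre-whitened powers equal the pseudo-Z and NAI scores", {
  set.seed(131)
  for (i in 1:10) {
    n <- sample(5:15, 1)
    l <- rnorm(n)
    R <- random_pd(n)
    N <- random_pd(n)
    sc <- beamformer_scores(l, R, N)
    expect_equal(sc$whitened_power[["AG"]], sc$nai,
                 tolerance = 1e-8)
    expect_equal(sc$whitened_power[["UNG"]], sc$pseudo_z,
                 tolerance = 1e-8)
    expect_true(sc$pseudo_z > 0 && sc$nai > 0)
  }
})

test_that("isotropic noise makes the AG power a sigma^2 multiple of the NAI", {
  set.seed(132)
  l <- rnorm(8)
  R <- random_pd(8)
  sigma2 <- 2.7
  sc <- beamformer_scores(l, R, sigma2 * diag(8))
  expect_equal(sc$projected_power[["AG"]], sigma2 * sc$nai, tolerance = 1e-8)
  expect_error(beamformer_scores(l, R, diag(c(rep(1, 7), -1))),
               "positive definite")
})
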