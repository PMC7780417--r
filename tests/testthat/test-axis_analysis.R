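# Axis geometry, hyperspherical coordinates, bootstrap reliability and
# population scalograms.

test_that("angle_between is symmetric, sign- and rotation-invariant", {
  set.seed(1)
  b1 <- rnorm(50); b1 <- b1 / sqrt(sum(b1^2))
  expect_equal(angle_between(b1, b1), 0)
  expect_equal(angle_between(b1, -b1), 0)
  u <- rnorm(50); u <- u - sum(u * b1) * b1; u <- u / sqrt(sum(u^2))
  expect_equal(angle_between(b1, u), 90, tolerance = 1e-10)
  b60 <- cos(pi / 3) * b1 + sin(pi / 3) * u
  expect_equal(angle_between(b1, b60), 60, tolerance = 1e-10)
  expect_equal(angle_between(b60, b1), angle_between(b1, b60))
  expect_equal(angle_between(3 * b1, -7 * b60), 60, tolerance = 1e-10)
  # common rotation invariance
  Q <- qr.Q(qr(matrix(rnorm(2500), 50, 50)))
  expect_equal(angle_between(Q %*% b1, Q %*% b60), 60, tolerance = 1e-8)
  expect_error(angle_between(rep(0, 3), c(1, 0, 0)), "zero vector")
})

test_that("angles from random axes stay within [0, 90]", {
  set.seed(2)
  for (i in 1:20) {
    a <- angle_between(rnorm(10), rnorm(10))
    expect_gte(a, 0); expect_lte(a, 90)
  }
})

test_that("hyperspherical coordinates follow the stated convention", {
  expect_equal(to_spherical(c(1, 0, 0, 0)), rep(0, 3))
  # textbook 3D: (0,0,1) -> polar pi/2, azimuth pi/2
  expect_equal(to_spherical(c(0, 0, 1)), c(pi / 2, pi / 2))
  expect_equal(length(to_spherical(make_axes(128, 30, 1)$b1)), 127L)
  expect_error(to_spherical(c(1, 1)), "unit norm")
})

test_that("spherical round trip is exact for random unit vectors", {
  set.seed(3)
  for (i in 1:100) {
    v <- rnorm(128); v <- v / sqrt(sum(v^2))
    ang <- to_spherical(v)
    expect_true(all(ang[1:126] >= 0 & ang[1:126] <= pi))
    expect_lt(max(abs(from_spherical(ang) - v)), 1e-10)
  }
  # low dimension too
  v <- c(-0.6, 0.8)
  expect_lt(max(abs(from_spherical(to_spherical(v)) - v)), 1e-12)
})

test_that("bootstrap on zero-variability trials returns the full-data axis", {
  ex <- simulate_experiment(synthetic_config(
    N = 40, trials_per_stimulus = 5, snr_db = Inf, seed = 4))
  boot <- bootstrap_axes(ex$trials, list(phi = ex$phi, psi = ex$psi),
                         B = 10, seed = 5)
  for (nm in c("phi", "psi"))
    expect_lt(max(abs(sweep(boot$replicates[[nm]], 2,
                            boot$full[[nm]]))), 1e-10)
})

test_that("bootstrap replicate means are stable across seeds", {
  ex <- simulate_experiment(synthetic_config(
    N = 40, trials_per_stimulus = 60, snr_db = 0, seed = 6))
  b1 <- bootstrap_axes(ex$trials, list(phi = ex$phi, psi = ex$psi),
                       B = 40, seed = 7)
  b2 <- bootstrap_axes(ex$trials, list(phi = ex$phi, psi = ex$psi),
                       B = 40, seed = 8)
  m1 <- colMeans(b1$replicates$phi); m2 <- colMeans(b2$replicates$phi)
  expect_lt(angle_between(m1, m2), 10)
  # replicates differ between seeds
  expect_gt(max(abs(b1$replicates$phi - b2$replicates$phi)), 1e-6)
})

test_that("well-separated bootstrap clusters give zero LDA errors", {
  ex <- simulate_experiment(synthetic_config(
    N = 40, theta_deg = 80, trials_per_stimulus = 100, snr_db = 30,
    seed = 9))
  boot <- bootstrap_axes(ex$trials, list(phi = ex$phi, psi = ex$psi),
                         B = 30, seed = 10)
  rel <- axis_reliability(boot)
  expect_equal(rel$misclassifications, 0)
  expect_gt(rel$variance_fraction, 0)
  expect_lte(rel$variance_fraction, 1)
})

test_that("indistinguishable axes give chance-level LDA errors", {
  # second attribute = first plus a tiny fixed perturbation: the two
  # groups estimate essentially the same direction, so their bootstrap
  # clouds coincide and LDA cannot beat chance (B of 2B)
  ex <- simulate_experiment(synthetic_config(
    N = 30, trials_per_stimulus = 40, snr_db = -5, seed = 11))
  set.seed(99)
  y2 <- ex$phi + rnorm(5, sd = 0.01 * sd(ex$phi))
  boot <- bootstrap_axes(ex$trials, list(g1 = ex$phi, g2 = y2),
                         B = 40, seed = 12)
  rel <- axis_reliability(boot)
  expect_gt(rel$misclassifications, 20)
  # exactly affinely related attributes collapse the clouds pointwise;
  # depending on rounding this is either flagged degenerate or lands at
  # chance level — never a confident separation
  boot2 <- bootstrap_axes(ex$trials,
                          list(g1 = ex$phi, g2 = 2 * ex$phi + 3),
                          B = 40, seed = 13)
  rel2 <- tryCatch(axis_reliability(boot2), error = function(e) e)
  if (inherits(rel2, "error")) {
    expect_match(conditionMessage(rel2), "degenerate")
  } else {
    expect_gt(rel2$misclassifications, 20)
  }
  # noiseless trials: every replicate identical, PCA degenerates
  ex0 <- simulate_experiment(synthetic_config(
    N = 20, trials_per_stimulus = 4, snr_db = Inf, seed = 14))
  boot0 <- bootstrap_axes(ex0$trials, list(g1 = ex0$phi, g2 = ex0$psi),
                          B = 5, seed = 15)
  expect_error(axis_reliability(boot0), "degenerate")
})

test_that("population_scalogram equals brute-force root-sum-of-squares", {
  set.seed(13)
  axes <- lapply(1:11, function(i) rnorm(128))
  out <- population_scalogram(axes)
  oracle <- sqrt(colSums(do.call(rbind, axes)^2))   # direct loop
  expect_equal(out, oracle, tolerance = 1e-12)
  # single-entry cases
  one <- rep(0, 16); one[5] <- -3
  expect_equal(population_scalogram(list(one))[5], 3)
  expect_equal(population_scalogram(list(one, one))[5], sqrt(2) * 3)
  # layout attachment
  layout <- wavelet_layout(2048, 5000)
  fv <- population_scalogram(axes, layout)
  expect_s3_class(fv, "feature_vector")
  expect_error(population_scalogram(list(1:3, 1:4)), "differing lengths")
})

test_that("planted-angle recovery and slope-angle correlation", {
  # noiseless: fitted angle equals planted angle to 1e-6 degrees
  for (theta in c(15, 60)) {
    ex <- simulate_experiment(synthetic_config(
      N = 64, theta_deg = theta, trials_per_stimulus = 3, snr_db = Inf,
      seed = 14))
    X <- t(vapply(ex$trials, colMeans, numeric(64)))
    fphi <- roldsis(observation_set(X, ex$phi))
    fpsi <- roldsis(observation_set(X, ex$psi))
    expect_equal(angle_between(fphi$b_hat, fpsi$b_hat), theta,
                 tolerance = 1e-6 / theta)
  }
  # population in which the planted angle grows with psychometric slope:
  # recovered angle correlates positively with max_slope
  betas <- seq(0.08, 0.4, length.out = 8)
  thetas <- seq(20, 75, length.out = 8)
  got <- vapply(seq_along(betas), function(i) {
    ex <- simulate_experiment(synthetic_config(
      N = 48, theta_deg = thetas[i], beta = -betas[i],
      trials_per_stimulus = 30, snr_db = 5, seed = 100 + i))
    X <- t(vapply(ex$trials, colMeans, numeric(48)))
    angle_between(roldsis(observation_set(X, ex$phi))$b_hat,
                  roldsis(observation_set(X, ex$psi))$b_hat)
  }, numeric(1))
  slopes <- max_slope(list(beta = betas))
  expect_gt(cor(slopes, got), 0)
})
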