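# Fold construction, regularized fitters, CV machinery, tuning and the
# overdetermined sweep.

make_noisy_trials <- function(N = 32, tps = 12, snr_db = 5, seed = 1) {
  simulate_experiment(synthetic_config(
    N = N, trials_per_stimulus = tps, snr_db = snr_db, seed = seed))
}

test_that("make_folds balances and is deterministic", {
  plan <- make_folds(rep(10, 5), k = 5, seed = 3)
  sizes <- sapply(plan$assignment, tabulate, nbins = 5)
  expect_true(all(sizes == 2))
  plan2 <- make_folds(rep(10, 5), k = 5, seed = 3)
  expect_identical(plan$assignment, plan2$assignment)
  # 7 trials into 3 folds: sizes {3,2,2}
  plan3 <- make_folds(7, k = 3, seed = 1)
  expect_equal(sort(tabulate(plan3$assignment[[1]], 3)), c(2, 2, 3))
  expect_error(make_folds(c(10, 2), k = 3), "at least k")
  expect_error(make_folds(10, k = 1), "at least 2")
})

test_that("ridge dual form equals the primal closed form", {
  set.seed(4)
  X <- matrix(rnorm(5 * 128), 5, 128); y <- rnorm(5)
  for (lam in c(1e-3, 1, 100)) {
    dual <- ridge_fit(X, y, lam)
    Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
    b_primal <- solve(crossprod(Xc) + lam * diag(128), crossprod(Xc, yc))
    expect_equal(dual$b, drop(b_primal), tolerance = 1e-8)
  }
})

test_that("ridge limits: OLS at lambda 0, shrinkage to the mean at infinity", {
  set.seed(5)
  X <- matrix(rnorm(10 * 2), 10, 2); y <- rnorm(10)
  r0 <- ridge_fit(X, y, 0)
  ols <- lm(y ~ X)
  expect_equal(r0$b, unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(r0$a, unname(coef(ols)[1]), tolerance = 1e-8)
  # |b| decreases monotonically in lambda, to zero
  norms <- sapply(10^seq(-2, 6, by = 1),
                  function(l) sqrt(sum(ridge_fit(X, y, l)$b^2)))
  expect_true(all(diff(norms) < 1e-12))
  expect_lt(norms[length(norms)], 1e-4)
})

test_that("lasso shrinks everything to zero above the critical lambda", {
  set.seed(6)
  X <- matrix(rnorm(20 * 10), 20, 10); y <- rnorm(20)
  lam_max <- max(abs(crossprod(scale(X, scale = FALSE),
                               y - mean(y)))) / nrow(X)
  f <- lasso_fit(X, y, 2 * lam_max)
  expect_true(all(f$b == 0))
  f2 <- lasso_fit(X, y, lam_max / 100)
  expect_gt(sum(f2$b != 0), 0)
  expect_error(lasso_fit(X, y, -1), "non-negative")
})

test_that("spls extracts sparse directions and interpolates with full K", {
  set.seed(7)
  X <- matrix(rnorm(6 * 40), 6, 40); y <- rnorm(6)
  f <- spls_fit(X, y, zeta = 0.7, K = 2)
  expect_true(any(f$directions == 0))      # sparsity active
  expect_equal(sum(f$directions[, 1]^2), 1, tolerance = 1e-10)
  # zeta = 0, K = M-1: dense PLS spans the row space -> exact fit
  f2 <- spls_fit(X, y, zeta = 0, K = 5)
  expect_lt(max(abs(y - f2$a - X %*% f2$b)), 1e-6)
  expect_error(spls_fit(X, y, zeta = 1, K = 1), "zeta")
  expect_error(spls_fit(X, y, zeta = 0.5, K = 6), "K must lie")
})

test_that("cv_error matches a hand-rolled loop and is label-invariant", {
  ex <- make_noisy_trials(seed = 8)
  plan <- make_folds(sapply(ex$trials, nrow), k = 3, seed = 9)
  res <- cv_error("roldsis", plan, ex$trials, ex$phi)
  expect_equal(res$mse, mean(res$fold_mse))
  expect_true(all(res$fold_mse >= 0))
  # independent oracle: explicit loop over folds
  oracle <- sapply(1:3, function(f) {
    tr_X <- do.call(rbind, lapply((1:3)[-f], function(g)
      t(sapply(seq_along(ex$trials), function(s) {
        a <- plan$assignment[[s]]
        colMeans(ex$trials[[s]][a == g, , drop = FALSE])
      }))))
    tr_y <- rep(ex$phi, 2)
    te_X <- t(sapply(seq_along(ex$trials), function(s) {
      a <- plan$assignment[[s]]
      colMeans(ex$trials[[s]][a == f, , drop = FALSE])
    }))
    fit <- roldsis(observation_set(tr_X, tr_y))
    mean((predict(fit, te_X) - ex$phi)^2)
  })
  expect_equal(res$fold_mse, oracle, tolerance = 1e-10)
  # permuting fold labels leaves the mean MSE unchanged
  perm <- c(2, 3, 1)
  plan_p <- plan
  plan_p$assignment <- lapply(plan$assignment, function(a) perm[a])
  res_p <- cv_error("roldsis", plan_p, ex$trials, ex$phi)
  expect_equal(sort(res_p$fold_mse), sort(res$fold_mse), tolerance = 1e-10)
})

test_that("noiseless data give near-zero roldsis CV error", {
  ex <- simulate_experiment(synthetic_config(
    N = 32, trials_per_stimulus = 12, snr_db = Inf, seed = 10))
  plan <- make_folds(sapply(ex$trials, nrow), k = 3, seed = 11)
  res <- cv_error("roldsis", plan, ex$trials, ex$phi)
  expect_lt(res$mse, 1e-12)
})

test_that("ridge at huge lambda predicts the training mean", {
  ex <- make_noisy_trials(seed = 12)
  plan <- make_folds(sapply(ex$trials, nrow), k = 3, seed = 13)
  res <- cv_error("ridge", plan, ex$trials, ex$phi,
                  params = list(lambda = 1e12))
  expect_equal(res$mse, mean((ex$phi - mean(ex$phi))^2),
               tolerance = 0.01)
})

test_that("tune finds the grid-scan argmin and rejects roldsis", {
  ex <- make_noisy_trials(N = 24, tps = 9, snr_db = 0, seed = 14)
  plan <- make_folds(sapply(ex$trials, nrow), k = 3, seed = 15)
  best <- tune("ridge", plan, ex$trials, ex$phi,
               lambda_range = c(1e-4, 1e4))
  # dense grid oracle
  grid <- 10^seq(-4, 4, length.out = 60)
  mses <- sapply(grid, function(l)
    cv_error("ridge", plan, ex$trials, ex$phi,
             params = list(lambda = l))$mse)
  expect_lte(best$mse, min(mses) * (1 + 1e-3))
  expect_error(tune("roldsis", plan, ex$trials, ex$phi), "no tunable")
})

test_that("spls tuning searches K and zeta", {
  ex <- make_noisy_trials(N = 24, tps = 9, snr_db = 3, seed = 16)
  plan <- make_folds(sapply(ex$trials, nrow), k = 3, seed = 17)
  best <- tune("spls", plan, ex$trials, ex$phi, K_max = 3)
  expect_true(best$params$K %in% 1:3)
  expect_gte(best$params$zeta, 0)
  expect_lt(best$params$zeta, 1)
})

test_that("roldsis CV error is comparable to tuned ridge at matched noise", {
  ex <- make_noisy_trials(N = 32, tps = 12, snr_db = 5, seed = 18)
  plan <- make_folds(sapply(ex$trials, nrow), k = 3, seed = 19)
  rr <- cv_error("roldsis", plan, ex$trials, ex$phi)$mse
  rg <- tune("ridge", plan, ex$trials, ex$phi)$mse
  # same order of magnitude (the two methods behave similarly here)
  expect_lt(rr, 10 * rg)
})

test_that("overdetermined sweep: partition bookkeeping and noise averaging", {
  ex <- simulate_experiment(synthetic_config(
    N = 16, trials_per_stimulus = 40, snr_db = 0, seed = 20))
  sweep_res <- overdetermined_sweep(ex$trials, ex$phi, sizes = c(1, 4),
                                    seed = 21)
  expect_equal(sweep_res$n_observations, c(200, 50))
  expect_true(all(sweep_res$rms >= 0))
  # noiseless: zero RMS at every size
  ex0 <- simulate_experiment(synthetic_config(
    N = 16, trials_per_stimulus = 40, snr_db = Inf, seed = 22))
  s0 <- overdetermined_sweep(ex0$trials, ex0$phi, sizes = c(1, 2), seed = 23)
  expect_lt(max(s0$rms), 1e-8)
  # averaging more trials per observation reduces RMS (seed battery)
  wins <- sapply(1:5, function(s) {
    exn <- simulate_experiment(synthetic_config(
      N = 16, trials_per_stimulus = 40, snr_db = 0, seed = 30 + s))
    r <- overdetermined_sweep(exn$trials, exn$phi, sizes = c(1, 6),
                              seed = 40 + s)
    r$rms[2] < r$rms[1]
  })
  expect_gte(sum(wins), 4)
  expect_error(overdetermined_sweep(ex$trials, ex$phi, sizes = 40),
               "not overdetermined")
})
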