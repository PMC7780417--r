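#' Stratified fold plan for cross-validation
#'
#' Randomly partitions each stimulus's trials into k folds of
#' near-equal size (sizes differ by at most one within a stimulus).
#'
#' @param trial_counts integer vector, number of trials per stimulus.
#' @param k number of folds, at least 2; every stimulus must have at
#'   least k trials.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return Object of class \code{fold_plan}: list with \code{k},
#'   \code{assignment} (list of integer vectors, fold id per trial) and
#'   \code{seed}.
#' @export
make_folds <- function(trial_counts, k, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("make_folds: k must be at least 2")
  if (any(trial_counts < k))
    stop("make_folds: every stimulus needs at least k = ", k, " trials")
  set.seed(as.integer(seed))
  assignment <- lapply(trial_counts, function(n) {
    sample(rep_len(seq_len(k), n))
  })
  structure(list(k = k, assignment = assignment, seed = seed),
            class = "fold_plan")
}

# per-stimulus fold averages: list of matrices -> list over folds of
# M x N matrices (average of that stimulus's trials in that fold)
.fold_averages <- function(trials, plan) {
  lapply(seq_len(plan$k), function(f) {
    t(mapply(function(tr, a) colMeans(tr[a == f, , drop = FALSE]),
             trials, plan$assignment))
  })
}

# --- regularized fitters ----------------------------------------------

#' Ridge regression in closed form
#'
#' Solves min ||yc - Xc b||^2 + lambda ||b||^2 on centered data, using
#' the M x M dual form b = Xc'(Xc Xc' + lambda I)^{-1} yc, which is
#' efficient and exact when N >> M; the intercept is recovered from the
#' centering.  At lambda = 0 on an overdetermined full-rank problem this
#' reduces to ordinary least squares (solved via the primal form).
#'
#' @param X numeric matrix M x N; \code{y} length-M response;
#'   \code{lambda} non-negative penalty.
#' @param y,lambda see above.
#' @return List with intercept \code{a} and coefficient vector \code{b}.
#' @export
ridge_fit <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (lambda < 0) stop("ridge_fit: lambda must be non-negative")
  m <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, m); yc <- y - ybar
  M <- nrow(X); N <- ncol(X)
  if (N >= M) {
    K <- Xc %*% t(Xc)
    if (lambda == 0) {
      alpha <- MASS::ginv(K) %*% yc       # minimum-norm limit
    } else {
      alpha <- solve(K + lambda * diag(M), yc)
    }
    b <- drop(crossprod(Xc, alpha))
  } else {
    b <- drop(solve(crossprod(Xc) + lambda * diag(N), crossprod(Xc, yc)))
  }
  list(a = ybar - sum(b * m), b = b)
}

#' Lasso regression at a fixed penalty
#'
#' Thin adapter over the coordinate-descent solver of \pkg{glmnet}
#' (gaussian family, unstandardized), returning the intercept and
#' coefficients at the requested lambda.  Note glmnet's objective is
#' (1/2M)||y - a - Xb||^2 + lambda ||b||_1.
#'
#' @param X matrix M x N; \code{y} length-M response; \code{lambda}
#'   non-negative penalty.
#' @param y,lambda see above.
#' @return List with \code{a} and \code{b}.
#' @export
lasso_fit <- function(X, y, lambda) {
  if (lambda < 0) stop("lasso_fit: lambda must be non-negative")
  fit <- glmnet::glmnet(as.matrix(X), y, family = "gaussian",
                        alpha = 1, lambda = lambda,
                        standardize = FALSE, thresh = 1e-10)
  list(a = as.numeric(fit$a0),
       b = as.numeric(fit$beta[, 1L]))
}

#' Sparse partial least squares regression
#'
#' Native NIPALS-style sparse PLS with soft-thresholded direction
#' vectors: at each of K components, the covariance direction
#' w = Xc'yc is soft-thresholded at \code{zeta} times its largest
#' absolute entry (zeta in (0,1); larger means sparser), normalized,
#' and the response and predictors are deflated by the extracted score.
#' The final coefficients are the least-squares regression of y on the
#' K scores mapped back to the original features.
#'
#' @param X matrix M x N; \code{y} length-M response.
#' @param y response vector.
#' @param zeta sparsity parameter in [0, 1).
#' @param K number of latent components, 1..M-1.
#' @return List with \code{a}, \code{b} and \code{directions} (N x K).
#' @export
spls_fit <- function(X, y, zeta, K) {
  X <- as.matrix(X)
  if (zeta < 0 || zeta >= 1) stop("spls_fit: zeta must lie in [0, 1)")
  K <- as.integer(K)
  if (K < 1L || K > nrow(X) - 1L)
    stop("spls_fit: K must lie in 1..M-1")
  m <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, m); yc <- y - ybar
  N <- ncol(X)
  W <- matrix(0, N, K)    # sparse weight vectors
  P <- matrix(0, N, K)    # loadings
  Tm <- matrix(0, nrow(X), K)
  Xd <- Xc; yd <- yc
  for (k in seq_len(K)) {
    w <- drop(crossprod(Xd, yd))
    thr <- zeta * max(abs(w))
    w <- sign(w) * pmax(abs(w) - thr, 0)
    if (all(w == 0)) { K <- k - 1L; break }
    w <- w / sqrt(sum(w^2))
    tk <- drop(Xd %*% w)
    tt <- sum(tk^2)
    if (tt < 1e-300) { K <- k - 1L; break }
    p <- drop(crossprod(Xd, tk)) / tt
    W[, k] <- w; P[, k] <- p; Tm[, k] <- tk
    Xd <- Xd - tk %o% p
    yd <- yd - tk * sum(tk * yd) / tt
  }
  if (K == 0L) return(list(a = ybar - 0, b = numeric(N),
                           directions = W[, 0, drop = FALSE]))
  W <- W[, seq_len(K), drop = FALSE]
  P <- P[, seq_len(K), drop = FALSE]
  Tm <- Tm[, seq_len(K), drop = FALSE]
  # b = W (P'W)^{-1} q, q = regression of yc on scores
  q <- drop(solve(crossprod(Tm), crossprod(Tm, yc)))
  b <- drop(W %*% solve(crossprod(P, W), q))
  list(a = ybar - sum(b * m), b = b, directions = W)
}

# dispatch a fitter; params is a named list
.fit_method <- function(method, X, y, params) {
  switch(method,
    roldsis = {
      f <- tryCatch(roldsis(observation_set(X, y)),
                    error = function(e) e)
      if (inherits(f, "error")) {
        # duplicated fold averages (e.g. noiseless trials) make the
        # stacked system rank-deficient but still consistent; fall back
        # to the minimum-norm exact solve, which coincides with the
        # spanned-subspace solution on the distinct observations
        if (!grepl("rank-deficient", conditionMessage(f))) stop(f)
        m <- colMeans(X); ybar <- mean(y)
        b <- drop(MASS::ginv(sweep(X, 2L, m)) %*% (y - ybar))
        a <- ybar - sum(b * m)
        resid <- y - a - drop(X %*% b)
        if (max(abs(resid)) > 1e-6 * (1 + max(abs(y)))) stop(f)
        list(a = a, b = b)
      } else list(a = f$a, b = f$b)
    },
    ridge = ridge_fit(X, y, params$lambda),
    lasso = lasso_fit(X, y, params$lambda),
    spls = spls_fit(X, y, params$zeta, params$K),
    stop("unknown method: ", method))
}

#' Cross-validated prediction error
#'
#' For each fold in turn: the training observations are the per-stimulus
#' averages of the trials in each of the k - 1 remaining folds (giving
#' M (k-1) observations, with each stimulus's attribute repeated), the
#' test observations are the per-stimulus averages of the held-out fold,
#' and the mean squared prediction error is recorded.  All methods see
#' identical training and test sets.
#'
#' @param method one of "roldsis", "ridge", "lasso", "spls".
#' @param folds a [make_folds()] plan.
#' @param trials list of M matrices (trials x features), one per
#'   stimulus.
#' @param y length-M attribute vector.
#' @param params named list of method parameters (\code{lambda} for
#'   ridge/lasso; \code{zeta}, \code{K} for spls; empty for roldsis).
#' @return Object of class \code{cv_result}: list with \code{method},
#'   \code{k}, \code{params}, \code{fold_mse} (length-k), \code{mse}
#'   (their mean).
#' @export
cv_error <- function(method, folds, trials, y, params = list()) {
  stopifnot(inherits(folds, "fold_plan"))
  trials <- lapply(trials, as.matrix)
  M <- length(trials)
  if (length(y) != M) stop("cv_error: one attribute per stimulus required")
  favg <- .fold_averages(trials, folds)
  fold_mse <- vapply(seq_len(folds$k), function(f) {
    train_X <- do.call(rbind, favg[-f])
    train_y <- rep(y, times = folds$k - 1L)
    # rows of favg[[g]] are stimuli; stacking keeps stimulus order per fold
    fit <- .fit_method(method, train_X, train_y, params)
    test_X <- favg[[f]]
    pred <- drop(fit$a + test_X %*% fit$b)
    mean((pred - y)^2)
  }, numeric(1L))
  structure(list(method = method, k = folds$k, params = params,
                 fold_mse = fold_mse, mse = mean(fold_mse)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("CV result [", x$method, "], k = ", x$k, ": mean MSE = ",
      signif(x$mse, 5), "\n", sep = "")
  if (length(x$params))
    cat("  params:", paste(names(x$params), signif(unlist(x$params), 4),
                           sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Tune a regularized method by CV-error minimization
#'
#' Scalar penalties (ridge, lasso) are minimized over log10(lambda) by
#' bracketed golden-section search (\code{stats::optimize}), a
#' derivative-free choice suited to the noisy, non-smooth CV objective;
#' bracket endpoints are also evaluated so boundary optima are returned.
#' SPLS is tuned by exhaustive search over K = 1..K_max crossed with the
#' same 1-D search over zeta.  RoLDSIS has no tunable parameter and is
#' rejected.
#'
#' @param method "ridge", "lasso" or "spls".
#' @param folds,trials,y as in [cv_error()].
#' @param lambda_range length-2 positive bracket for lambda.
#' @param zeta_range bracket for the SPLS sparsity parameter.
#' @param K_max largest SPLS component count tried (capped at M - 1).
#' @return The best \code{cv_result}, with tuned parameters recorded.
#' @export
tune <- function(method, folds, trials, y,
                 lambda_range = c(1e-6, 1e6),
                 zeta_range = c(0, 0.99), K_max = NULL) {
  if (method == "roldsis")
    stop("tune: roldsis has no tunable parameter")
  obj_scalar <- function(par_name, transform = identity) {
    function(v) cv_error(method, folds, trials, y,
                         params = stats::setNames(list(transform(v)),
                                                  par_name))$mse
  }
  if (method %in% c("ridge", "lasso")) {
    f <- obj_scalar("lambda", function(v) 10^v)
    br <- log10(lambda_range)
    op <- stats::optimize(f, br, tol = 1e-3)
    cand <- c(op$minimum, br)
    vals <- c(op$objective, f(br[1L]), f(br[2L]))
    best <- cand[which.min(vals)]
    return(cv_error(method, folds, trials, y,
                    params = list(lambda = 10^best)))
  }
  if (method == "spls") {
    M <- length(trials)
    if (is.null(K_max)) K_max <- M - 1L
    K_max <- min(K_max, M - 1L)
    best <- NULL
    for (K in seq_len(K_max)) {
      f <- function(z) cv_error(method, folds, trials, y,
                                params = list(zeta = z, K = K))$mse
      op <- stats::optimize(f, zeta_range, tol = 1e-3)
      cand <- c(op$minimum, zeta_range)
      vals <- c(op$objective, f(zeta_range[1L]), f(zeta_range[2L]))
      z <- cand[which.min(vals)]
      res <- cv_error(method, folds, trials, y,
                      params = list(zeta = z, K = K))
      if (is.null(best) || res$mse < best$mse) best <- res
    }
    return(best)
  }
  stop("tune: unknown method ", method)
}

#' Ordinary least squares at varying trials-per-observation
#'
#' Explores the overdetermined alternative to averaging: trials are
#' randomly partitioned into observations of \code{sizes} trials each
#' (averaged within a group), and when the resulting observation count
#' exceeds the feature count, ordinary least squares is fitted and the
#' in-sample root-mean-square prediction error reported.  On noisy data
#' the RMS error shrinks as the group size grows, illustrating the
#' noise-averaging trade-off.
#'
#' @param trials list of M matrices (trials x features).
#' @param y length-M attribute vector.
#' @param sizes integer vector of trials-per-observation settings.
#' @param seed integer seed for the random grouping.
#' @return data.frame with columns \code{trials_per_observation},
#'   \code{n_observations}, \code{rms}.
#' @export
overdetermined_sweep <- function(trials, y, sizes = 1:6, seed = 1L) {
  trials <- lapply(trials, as.matrix)
  N <- ncol(trials[[1L]])
  set.seed(as.integer(seed))
  out <- lapply(sizes, function(g) {
    obs <- list(); yy <- numeric(0)
    for (s in seq_along(trials)) {
      tr <- trials[[s]]
      n <- nrow(tr)
      ngrp <- n %/% g
      if (ngrp < 1L) stop("overdetermined_sweep: fewer than ", g,
                          " trials for stimulus ", s)
      idx <- sample.int(n)[seq_len(ngrp * g)]   # partition; remainder dropped
      grp <- matrix(idx, nrow = g)
      for (j in seq_len(ngrp)) {
        obs[[length(obs) + 1L]] <-
          colMeans(tr[grp[, j], , drop = FALSE])
        yy <- c(yy, y[s])
      }
    }
    X <- do.call(rbind, obs)
    if (nrow(X) <= N)
      stop("overdetermined_sweep: ", nrow(X),
           " observations do not exceed ", N,
           " features; system is not overdetermined")
    fit <- stats::lm.fit(cbind(1, X), yy)
    data.frame(trials_per_observation = g,
               n_observations = nrow(X),
               rms = sqrt(mean(fit$residuals^2)))
  })
  do.call(rbind, out)
}
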