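#' Configuration of a synthetic ERP experiment
#'
#' Collects the parameters of the generator, with defaults emulating the
#' reference phonemic-identification experiment: 5 stimuli presented 200
#' times each, 2048-sample epochs at 5 kHz, 128 retained wavelet
#' features, raw-trial SNR of -12 dB, physical attributes (VOT, ms) on
#' the -52..+16 ms continuum, psychophysical attributes (proportion of
#' /ta/ identifications) 0, 0.05, 0.5, 0.95, 1.
#'
#' Interior VOT values are derived from the configured psychometric
#' curve via [select_stimuli()], mirroring per-participant calibration;
#' the defaults beta = -0.2 /ms (oriented so /ta/ probability rises with
#' VOT) and t0 = -22 ms reproduce a typical participant.
#'
#' @param N feature count.
#' @param M stimulus count (>= 3 for two distinct planted axes).
#' @param trials_per_stimulus trials generated per stimulus.
#' @param S epoch length in samples (time-domain option).
#' @param fs sampling rate, Hz.
#' @param theta_deg planted angle between the physical and
#'   psychophysical axes, degrees in (0, 90].
#' @param psi psychophysical attribute values (length M, in [0, 1]).
#' @param phi physical attribute values, ms; \code{NULL} derives them
#'   from (\code{beta}, \code{t0}) and \code{continuum}.
#' @param continuum VOT endpoints, ms.
#' @param snr_db target per-trial SNR in dB (noise calibrated to it).
#' @param beta,t0 psychometric parameters used for phi derivation and
#'   response simulation.
#' @param seed integer seed.
#' @return Object of class \code{synthetic_config}.
#' @export
synthetic_config <- function(N = 128L, M = 5L, trials_per_stimulus = 200L,
                             S = 2048L, fs = 5000, theta_deg = 45,
                             psi = c(0, 0.05, 0.5, 0.95, 1),
                             phi = NULL, continuum = c(-52, 16),
                             snr_db = -12, beta = -0.2, t0 = -22,
                             seed = 1L) {
  if (M < 3L) stop("synthetic_config: M must be >= 3 for two distinct axes")
  if (theta_deg < 0 || theta_deg > 90)
    stop("synthetic_config: theta_deg must lie in [0, 90]")
  if (length(psi) != M)
    stop("synthetic_config: psi must have one value per stimulus")
  if (is.null(phi)) {
    pf <- structure(list(beta = beta, t0 = t0, separated = FALSE),
                    class = "psychometric_fit")
    phi <- select_stimuli(pf, percents = 100 * psi, continuum = continuum)
  }
  if (length(phi) != M)
    stop("synthetic_config: phi must have one value per stimulus")
  structure(list(N = as.integer(N), M = as.integer(M),
                 trials_per_stimulus = as.integer(trials_per_stimulus),
                 S = as.integer(S), fs = fs, theta_deg = theta_deg,
                 psi = psi, phi = phi, continuum = continuum,
                 snr_db = snr_db, beta = beta, t0 = t0,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Plant two unit axes at a prescribed angle
#'
#' Draws a random unit vector b1 in R^N and constructs
#' b2 = cos(theta) b1 + sin(theta) u with u a random unit vector
#' orthogonal to b1, so that the angle between the two axes is exactly
#' \code{theta_deg}.
#'
#' @param N dimension.
#' @param theta_deg angle in [0, 90] degrees.
#' @param seed integer seed.
#' @return List with unit vectors \code{b1} and \code{b2}.
#' @export
make_axes <- function(N, theta_deg, seed = 1L) {
  if (theta_deg < 0 || theta_deg > 90)
    stop("make_axes: theta_deg must lie in [0, 90]")
  set.seed(as.integer(seed))
  b1 <- stats::rnorm(N); b1 <- b1 / sqrt(sum(b1^2))
  u <- stats::rnorm(N)
  u <- u - sum(u * b1) * b1
  u <- u / sqrt(sum(u^2))
  th <- theta_deg * pi / 180
  b2 <- cos(th) * b1 + sin(th) * u
  list(b1 = b1, b2 = b2 / sqrt(sum(b2^2)))
}

#' Construct noise-free stimulus templates
#'
#' Builds M template feature vectors satisfying both planted affine
#' relations exactly: phi_i = a_phi + b1' x_i and psi_i = a_psi + b2' x_i.
#' The templates live in an (M-1)-dimensional frame whose first two
#' directions span the planted axes; the first two template coordinates
#' are pinned by the constraints and the remaining M - 3 are drawn
#' randomly (re-drawn, up to 10 times, if the centered coordinates fall
#' short of rank M - 1).
#'
#' Requires a nonzero planted angle: at theta = 0 the two constraints
#' collapse onto one direction and are generally incompatible.
#'
#' @param config a [synthetic_config()].
#' @param axes result of [make_axes()] (unit vectors b1, b2).
#' @param coord_sd scale of the free template coordinates, in attribute
#'   units (matches the VOT spread so all frame directions carry
#'   comparable energy).
#' @return List with \code{templates} (M x N), \code{a_phi},
#'   \code{a_psi}, \code{frame} (N x (M-1)).
#' @export
make_templates <- function(config, axes, coord_sd = 25) {
  stopifnot(inherits(config, "synthetic_config"))
  M <- config$M; N <- config$N
  b1 <- axes$b1; b2 <- axes$b2
  th <- config$theta_deg * pi / 180
  if (sin(th) < 1e-12)
    stop("make_templates: planted angle must be nonzero to satisfy ",
         "two independent affine constraints")
  q1 <- b1
  q2 <- (b2 - cos(th) * b1) / sin(th)       # unit, orthogonal to b1
  for (attempt in seq_len(10L)) {
    # complete an orthonormal (M-1)-frame containing q1, q2
    Q <- cbind(q1, q2)
    while (ncol(Q) < M - 1L) {
      v <- stats::rnorm(N)
      v <- v - Q %*% crossprod(Q, v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) Q <- cbind(Q, v / nv)
    }
    # coordinates: t1 pinned by phi, t2 by psi, rest free
    Tc <- matrix(0, M, M - 1L)
    Tc[, 1L] <- config$phi
    Tc[, 2L] <- (config$psi - cos(th) * config$phi) / sin(th)
    if (M > 3L)
      Tc[, 3:(M - 1L)] <- stats::rnorm(M * (M - 3L), sd = coord_sd)
    sv <- svd(scale(Tc, scale = FALSE), nu = 0, nv = 0)$d
    if (sv[M - 1L] > 1e-10 * sv[1L]) break
    if (attempt == 10L)
      stop("make_templates: failed to obtain rank M-1 coordinates")
  }
  templates <- Tc %*% t(Q)                  # a_phi = a_psi = 0 here
  dimnames(templates) <- NULL
  list(templates = templates, a_phi = 0, a_psi = 0, frame = Q)
}

#' Add calibrated i.i.d. Gaussian noise to templates
#'
#' Generates \code{trials_per_stimulus} noisy trials per stimulus:
#' trial = template + epsilon, epsilon i.i.d. N(0, sigma^2) per feature,
#' with sigma calibrated so the mean per-trial SNR
#' 10 log10(template power / sigma^2) matches \code{config$snr_db}.
#' Averaging n trials then raises the SNR by 10 log10(n) dB in
#' expectation.
#'
#' @param config a [synthetic_config()].
#' @param templates M x N template matrix.
#' @return List of M matrices (trials x N); attribute
#'   \code{noise_sd} records the calibrated sigma.
#' @export
make_trials <- function(config, templates) {
  stopifnot(inherits(config, "synthetic_config"))
  P <- mean(templates^2)                    # mean template power per feature
  sigma <- if (is.infinite(config$snr_db) && config$snr_db > 0) 0
           else sqrt(P / 10^(config$snr_db / 10))
  out <- lapply(seq_len(nrow(templates)), function(i) {
    eps <- matrix(stats::rnorm(config$trials_per_stimulus * config$N,
                               sd = sigma),
                  config$trials_per_stimulus, config$N)
    sweep(eps, 2L, templates[i, ], `+`)
  })
  attr(out, "noise_sd") <- sigma
  out
}

#' Simulate binary identification responses
#'
#' Draws Bernoulli responses from the psychometric curve
#' p(t) = 100/(1 + exp(beta (t - t0))) at each presented VOT.  With
#' beta < 0 the /ta/ probability increases with VOT, the physiological
#' orientation.
#'
#' @param beta,t0 psychometric parameters (1/ms and ms).
#' @param vot_grid VOT values presented, ms.
#' @param n_per_vot presentations per grid value.
#' @param seed integer seed.
#' @return An [identification_data()].
#' @export
simulate_identification <- function(beta, t0, vot_grid,
                                    n_per_vot = 1L, seed = 1L) {
  if (n_per_vot < 1L) stop("simulate_identification: n_per_vot >= 1")
  set.seed(as.integer(seed))
  vot <- rep(vot_grid, each = n_per_vot)
  p <- .psy_curve(vot, beta, t0) / 100
  identification_data(vot, stats::rbinom(length(vot), 1L, p))
}

#' Generate a complete synthetic ERP experiment
#'
#' Chains [make_axes()], [make_templates()] and [make_trials()] under
#' one seed and returns trials together with the planted ground truth,
#' so that recovery can be verified exactly (zero noise) or
#' statistically (calibrated noise).
#'
#' @param config a [synthetic_config()].
#' @return Object of class \code{synthetic_experiment}: list with
#'   \code{config}, \code{b_phi}, \code{b_psi} (planted unit axes),
#'   \code{a_phi}, \code{a_psi}, \code{templates}, \code{trials} (list
#'   of M matrices), \code{phi}, \code{psi}, \code{noise_sd}.
#' @examples
#' ex <- simulate_experiment(synthetic_config(trials_per_stimulus = 20))
#' fit <- roldsis(observation_set(
#'   t(sapply(ex$trials, colMeans)), ex$phi))
#' angle_between(fit$b_hat, ex$b_phi)  # small
#' @export
simulate_experiment <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  axes <- make_axes(config$N, config$theta_deg, seed = config$seed)
  tmpl <- make_templates(config, axes)
  trials <- make_trials(config, tmpl$templates)
  structure(list(config = config,
                 b_phi = axes$b1, b_psi = axes$b2,
                 a_phi = tmpl$a_phi, a_psi = tmpl$a_psi,
                 templates = tmpl$templates,
                 trials = trials,
                 phi = config$phi, psi = config$psi,
                 noise_sd = attr(trials, "noise_sd")),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("Synthetic ERP experiment:", x$config$M, "stimuli x",
      x$config$trials_per_stimulus, "trials,", x$config$N, "features\n")
  cat("  planted angle:", x$config$theta_deg, "deg; per-trial SNR target:",
      x$config$snr_db, "dB (noise sd", signif(x$noise_sd, 4), ")\n")
  invisible(x)
}
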