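#' Bundle binary identification responses
#'
#' Stores (VOT, response) pairs from a two-alternative forced-choice
#' syllable identification task, where VOT is the stimulus voice onset
#' time in ms and response = 1 codes the voiceless (/ta/) percept.
#'
#' @param vot numeric vector, stimulus VOT in ms.
#' @param response vector of 0/1 responses, same length.
#' @export
identification_data <- function(vot, response) {
  vot <- as.numeric(vot)
  response <- as.numeric(response)
  if (length(vot) != length(response))
    stop("identification_data: vot and response lengths differ")
  if (!all(response %in% c(0, 1)))
    stop("identification_data: responses must be 0 or 1")
  if (!all(is.finite(vot)))
    stop("identification_data: non-finite VOT values")
  structure(list(vot = vot, response = response),
            class = "identification_data")
}

# p(t) = 100 / (1 + exp(beta (t - t0))), in percent
.psy_curve <- function(t, beta, t0) 100 / (1 + exp(beta * (t - t0)))

#' Fit the two-parameter psychometric curve
#'
#' Maximum-likelihood logistic fit of the sigmoid
#' p(t) = 100 / (1 + exp(beta (t - t0))) to binary identification
#' responses, via a binomial GLM on the logit scale.  The curve passes
#' 50% at the inflection point t0; beta (1/ms) controls the steepness.
#' The sign of beta is kept as fitted — a /ta/ probability increasing
#' with VOT yields beta < 0 under this parameterization — and derived
#' quantities such as [max_slope()] are orientation-invariant.
#'
#' Perfect or near separation (a step-like data set) drives |beta| to
#' infinity; fits with |beta| above \code{separation_cap} are flagged as
#' non-converged.
#'
#' @param data an [identification_data()].
#' @param separation_cap |beta| (1/ms) above which the fit is flagged as
#'   separated/divergent.
#' @return Object of class \code{psychometric_fit}: list with
#'   \code{beta}, \code{t0}, \code{se_beta}, \code{se_t0},
#'   \code{converged}, \code{separated}.
#' @examples
#' set.seed(1)
#' vot <- runif(200, -52, 16)
#' p <- 1 / (1 + exp(-0.2 * (vot + 22)))
#' d <- identification_data(vot, rbinom(200, 1, p))
#' fit_psychometric(d)
#' @export
fit_psychometric <- function(data, separation_cap = 10) {
  stopifnot(inherits(data, "identification_data"))
  if (length(unique(data$response)) < 2L)
    stop("fit_psychometric: need both response classes")
  gm <- suppressWarnings(
    stats::glm(response ~ vot, family = stats::binomial(),
               data = data.frame(vot = data$vot,
                                 response = data$response)))
  co <- stats::coef(gm)
  # logit P(response = 1) = b0 + b1 t;  P = 1/(1+exp(beta (t - t0)))
  # gives beta = -b1, t0 = -b0/b1
  beta <- -co[["vot"]]
  t0 <- -co[["(Intercept)"]] / co[["vot"]]
  vc <- stats::vcov(gm)
  se_beta <- sqrt(vc["vot", "vot"])
  # delta method for t0 = -b0/b1
  grad <- c(-1 / co[["vot"]], co[["(Intercept)"]] / co[["vot"]]^2)
  se_t0 <- sqrt(drop(t(grad) %*% vc %*% grad))
  separated <- !gm$converged || abs(beta) > separation_cap
  structure(list(beta = beta, t0 = t0,
                 se_beta = se_beta, se_t0 = se_t0,
                 converged = gm$converged && !separated,
                 separated = separated),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("Psychometric fit: beta =", signif(x$beta, 4), "/ms, t0 =",
      signif(x$t0, 4), "ms",
      if (x$separated) "(SEPARATION FLAG)" else "", "\n")
  cat("  max slope:", signif(max_slope(x), 4), "%/ms\n")
  invisible(x)
}

#' Invert the psychometric curve to select stimuli
#'
#' Returns the VOT values at which the fitted curve attains the requested
#' response percentages.  For 0 < p < 100 the sigmoid is inverted in
#' closed form, t = t0 + log(100/p - 1)/beta.  The asymptotes p = 0 and
#' p = 100 are never attained by the sigmoid; for those the endpoints of
#' the physical continuum are returned (in the reference experiment,
#' -52 ms and +16 ms).
#'
#' @param fit a \code{psychometric_fit}.
#' @param percents numeric vector in [0, 100]; the calibration default is
#'   c(0, 5, 50, 95, 100).
#' @param continuum length-2 numeric, the [lo, hi] VOT endpoints in ms.
#' @return Numeric vector of VOT values, ms.
#' @export
select_stimuli <- function(fit, percents = c(0, 5, 50, 95, 100),
                           continuum = c(-52, 16)) {
  stopifnot(inherits(fit, "psychometric_fit"))
  if (any(percents < 0 | percents > 100))
    stop("select_stimuli: percents must lie in [0, 100]")
  if (fit$beta == 0)
    stop("select_stimuli: flat psychometric curve (beta = 0) cannot be inverted")
  lo <- min(continuum); hi <- max(continuum)
  vapply(percents, function(p) {
    if (p == 0) return(if (fit$beta < 0) lo else hi)
    if (p == 100) return(if (fit$beta < 0) hi else lo)
    fit$t0 + log(100 / p - 1) / fit$beta
  }, numeric(1L))
}

#' Maximal slope of the psychometric curve
#'
#' The slope |dp/dt| is largest at the inflection point t0, where it
#' equals (100/4) |beta| in %/ms.  It quantifies the degree of
#' categorical perception: steeper curves mean sharper category
#' boundaries.
#'
#' @param fit a \code{psychometric_fit}, or a list with a \code{beta}
#'   element.
#' @return Maximal slope, %/ms (non-negative).
#' @export
max_slope <- function(fit) {
  abs(fit$beta) * 100 / 4
}
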