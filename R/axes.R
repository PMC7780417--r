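#' Angle between two axes
#'
#' An axis is a direction without orientation: b and -b are the same
#' axis.  The angle is therefore computed from the absolute normalized
#' dot product, acos(|b1'b2| / (|b1||b2|)), and lies in [0, 90] degrees.
#' 0 means indistinguishable axes, 90 means orthogonal ones.
#'
#' @param b1,b2 nonzero numeric vectors of equal length.
#' @return Angle in degrees.
#' @examples
#' angle_between(c(1, 0), c(1, 1))  # 45
#' @export
angle_between <- function(b1, b2) {
  n1 <- sqrt(sum(b1^2)); n2 <- sqrt(sum(b2^2))
  if (n1 == 0 || n2 == 0)
    stop("angle_between: zero vector has no direction")
  if (length(b1) != length(b2))
    stop("angle_between: vectors have different lengths")
  d <- abs(sum(b1 * b2)) / (n1 * n2)
  acos(min(d, 1)) * 180 / pi
}

#' Hyperspherical coordinates of a unit vector
#'
#' A unit vector in R^N has N - 1 degrees of freedom and is represented
#' by N - 1 angles under the standard recursive parameterization:
#' x1 = cos(a1), x2 = sin(a1) cos(a2), ..., xN = sin(a1)...sin(a_{N-2})
#' sin(a_{N-1}).  The first N - 2 (polar) angles lie in [0, pi]; the
#' last (azimuthal) angle lies in (-pi, pi].  The first basis vector e1
#' maps to all-zero angles.
#'
#' @param v unit vector (norm 1 to 1e-8).
#' @return Numeric vector of N - 1 angles, radians.
#' @seealso [from_spherical()] — exact inverse.
#' @export
to_spherical <- function(v) {
  n <- length(v)
  if (n < 2L) stop("to_spherical: need at least 2 components")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-8)
    stop("to_spherical: input is not unit norm")
  ang <- numeric(n - 1L)
  # tail norms: r_k = sqrt(v_k^2 + ... + v_n^2)
  tail_sq <- rev(cumsum(rev(v^2)))
  for (k in seq_len(n - 2L))
    ang[k] <- atan2(sqrt(max(tail_sq[k + 1L], 0)), v[k])
  ang[n - 1L] <- atan2(v[n], v[n - 1L])
  ang
}

#' Unit vector from hyperspherical coordinates
#'
#' Inverse of [to_spherical()]; the round trip reproduces the vector to
#' 1e-10.
#'
#' @param angles numeric vector of N - 1 angles, radians.
#' @return Unit vector of length N.
#' @export
from_spherical <- function(angles) {
  n <- length(angles) + 1L
  v <- numeric(n)
  s <- 1
  for (k in seq_len(n - 2L)) {
    v[k] <- s * cos(angles[k])
    s <- s * sin(angles[k])
  }
  v[n - 1L] <- s * cos(angles[n - 1L])
  v[n] <- s * sin(angles[n - 1L])
  v
}

#' Bootstrap re-estimation of neurophysiological axes
#'
#' Quantifies the sampling variability of fitted axes.  For each of B
#' replicates, every stimulus's trials are resampled with replacement
#' (keeping the trial count), the resampled trials are averaged into M
#' observations, and the spanned-subspace regression is fitted for each
#' attribute.  The resulting unit axes are sign-aligned to the full-data
#' axis (positive dot product) before storage, since antipodal points on
#' the hypersphere represent the same axis.
#'
#' @param trials list of M matrices (trials x features), one per
#'   stimulus.
#' @param attributes named list of numeric length-M vectors, one per
#'   attribute (e.g. \code{list(phi = ..., psi = ...)}).
#' @param B number of bootstrap replicates (the reference analysis uses
#'   100).
#' @param seed integer seed driving the resampling.
#' @param max_retries resamples yielding rank-deficient observation sets
#'   are redrawn up to this many times before erroring.
#' @return Object of class \code{bootstrap_axes}: list with
#'   \code{replicates} (named list of B x N matrices of unit axes),
#'   \code{full} (named list of full-data unit axes), \code{B},
#'   \code{seed}.
#' @export
bootstrap_axes <- function(trials, attributes, B = 100L, seed = 1L,
                           max_retries = 10L) {
  stopifnot(is.list(trials), length(trials) >= 2L)
  trials <- lapply(trials, as.matrix)
  if (B < 2L) stop("bootstrap_axes: B must be at least 2")
  if (any(vapply(trials, nrow, 1L) < 2L))
    stop("bootstrap_axes: every stimulus needs at least 2 trials")
  M <- length(trials)
  for (a in attributes)
    if (length(a) != M)
      stop("bootstrap_axes: each attribute needs one value per stimulus")
  avg_full <- t(vapply(trials, colMeans, numeric(ncol(trials[[1L]]))))
  full <- lapply(attributes, function(y)
    roldsis(observation_set(avg_full, y))$b_hat)
  set.seed(as.integer(seed))
  reps <- lapply(attributes, function(a)
    matrix(NA_real_, B, ncol(avg_full)))
  for (r in seq_len(B)) {
    for (attempt in seq_len(max_retries + 1L)) {
      avg <- t(vapply(trials, function(tr) {
        idx <- sample.int(nrow(tr), nrow(tr), replace = TRUE)
        colMeans(tr[idx, , drop = FALSE])
      }, numeric(ncol(avg_full))))
      fits <- tryCatch(
        lapply(attributes, function(y)
          roldsis(observation_set(avg, y))$b_hat),
        error = function(e) NULL)
      if (!is.null(fits)) break
      if (attempt > max_retries)
        stop("bootstrap_axes: repeated rank-deficient resamples")
    }
    for (nm in names(attributes)) {
      bh <- fits[[nm]]
      if (sum(bh * full[[nm]]) < 0) bh <- -bh   # sign-align
      reps[[nm]][r, ] <- bh
    }
  }
  structure(list(replicates = reps, full = full, B = B, seed = seed),
            class = "bootstrap_axes")
}

#' PCA-LDA reliability of bootstrap axes
#'
#' Assesses whether two sets of bootstrap axes (one per attribute) are
#' distinguishable directions rather than a statistical fluke.  All 2B
#' unit axes are transformed to hyperspherical coordinates (N - 1 angles
#' each); PCA (centered, unscaled) is applied to the pooled 2B x (N-1)
#' angle matrix; the scores on the first two principal components are
#' classified by two-class linear discriminant analysis; the
#' misclassification count against the known attribute labels measures
#' the overlap (0 = perfectly separated, about B = chance).
#'
#' @param boot a [bootstrap_axes()] result with exactly two attributes.
#' @return Object of class \code{axis_reliability}: list with
#'   \code{scores} (2B x 2 PC scores), \code{labels},
#'   \code{misclassifications}, \code{variance_fraction} (variance
#'   explained by the first two PCs), \code{separatrix} (coefficients
#'   w0 + w1 PC1 + w2 PC2 = 0 of the LDA boundary), \code{spherical}
#'   (the 2B x (N-1) angle matrix).
#' @export
axis_reliability <- function(boot) {
  stopifnot(inherits(boot, "bootstrap_axes"))
  if (length(boot$replicates) != 2L)
    stop("axis_reliability: exactly two attribute groups are required")
  nms <- names(boot$replicates)
  ang <- do.call(rbind, lapply(boot$replicates, function(Rm)
    t(apply(Rm, 1L, to_spherical))))
  labels <- factor(rep(nms, each = boot$B), levels = nms)
  pc <- stats::prcomp(ang, center = TRUE, scale. = FALSE)
  if (pc$sdev[1L] == 0)
    stop("axis_reliability: degenerate covariance (all axes identical)")
  scores <- pc$x[, 1:2, drop = FALSE]
  varfrac <- sum(pc$sdev[1:2]^2) / sum(pc$sdev^2)
  ld <- tryCatch(
    MASS::lda(scores, grouping = labels),
    error = function(e)
      stop("axis_reliability: degenerate covariance (the two groups ",
           "coincide): ", conditionMessage(e)))
  pred <- stats::predict(ld, scores)$class
  mis <- sum(pred != labels)
  # Fisher boundary in the 2D score plane: w'(x - mean of group means) = 0
  w <- drop(ld$scaling[, 1L])
  mid <- colMeans(ld$means)
  separatrix <- c(intercept = -sum(w * mid), w1 = w[1L], w2 = w[2L])
  structure(list(scores = scores, labels = labels,
                 misclassifications = mis,
                 variance_fraction = varfrac,
                 separatrix = separatrix,
                 spherical = ang),
            class = "axis_reliability")
}

#' @export
print.axis_reliability <- function(x, ...) {
  cat("Axis reliability:", x$misclassifications, "of", length(x$labels),
      "bootstrap axes misclassified by LDA\n")
  cat("  first two PCs explain",
      sprintf("%.1f%%", 100 * x$variance_fraction), "of variance\n")
  invisible(x)
}

#' Population root-sum-of-squares scalogram
#'
#' Aggregates axes across participants into one time-frequency picture:
#' the squared loading of each wavelet component is summed over axes and
#' the square root of each sum is returned.  Components that carry
#' energy consistently across the population stand out.
#'
#' @param axes list of numeric vectors of equal length (one fitted axis
#'   per participant).
#' @param layout optional [wavelet_layout()] to attach, enabling
#'   [scalogram()] rendering.
#' @return A \code{feature_vector} when \code{layout} is given,
#'   otherwise a plain numeric vector.
#' @export
population_scalogram <- function(axes, layout = NULL) {
  stopifnot(is.list(axes), length(axes) >= 1L)
  n <- length(axes[[1L]])
  if (any(vapply(axes, length, 1L) != n))
    stop("population_scalogram: axes have differing lengths")
  acc <- sqrt(Reduce(`+`, lapply(axes, function(b) b^2)))
  if (is.null(layout)) acc else feature_vector(acc, layout)
}
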