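#' Orthonormal basis of the subspace spanned by observations
#'
#' Computes the mean observation m and the M - 1 orthonormal principal
#' directions of the row-centered matrix, which together parameterize the
#' affine subspace spanned by the M observations.  The directions are
#' obtained by singular value decomposition of the centered matrix (better
#' conditioned than an eigendecomposition of the N x N covariance when
#' N >> M).
#'
#' Each basis vector's sign is fixed so that its largest-magnitude entry
#' is positive; downstream results (the fitted axis b) are invariant to
#' this convention.
#'
#' @param X numeric matrix, M x N, with linearly independent rows after
#'   centering.
#' @param rtol relative rank tolerance: an error is raised when the
#'   (M-1)-th singular value is at or below \code{rtol} times the largest,
#'   which signals collinear or duplicated observations.
#' @return A list with \code{m} (length-N mean vector) and \code{V}
#'   (N x (M-1) matrix with orthonormal columns).
#' @export
spanned_basis <- function(X, rtol = 1e-10) {
  X <- as.matrix(X)
  M <- nrow(X)
  if (M < 2L)
    stop("spanned_basis: need at least 2 observations")
  m <- colMeans(X)
  Xc <- sweep(X, 2L, m)
  sv <- svd(Xc, nu = 0L, nv = M - 1L)
  if (sv$d[M - 1L] <= rtol * sv$d[1L])
    stop("spanned_basis: rank-deficient observations (singular value ",
         format(sv$d[M - 1L]), " <= ", format(rtol), " * ",
         format(sv$d[1L]), "); rows are collinear or duplicated")
  V <- sv$v
  # sign convention: largest-|entry| of each column positive
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  list(m = m, V = V)
}

#' Exact spanned-subspace regression (RoLDSIS)
#'
#' Fits the affine model y = a + b'x under the constraint that the axis b
#' lies in the (M-1)-dimensional subspace spanned by the M observations.
#' Writing z_i = V'(x_i - m) for the subspace coordinates of the
#' observations, the model becomes y_i = c + d'z_i: M equations in the M
#' unknowns (c, d).  With linearly independent observations the system is
#' even-determined and is solved exactly by a dense direct solve; the axis
#' and intercept are then recovered as b = V d and a = c - d'V'm.  The fit
#' interpolates the data (zero in-sample residual) and coincides with the
#' minimum-norm exact solution of the underdetermined least-squares
#' problem.
#'
#' There are no tuning parameters: the method is the limiting case of
#' principal component regression in which all M - 1 components are kept.
#'
#' @param obs an [observation_set()].
#' @param rtol rank tolerance passed to [spanned_basis()].
#' @return An object of class \code{roldsis_fit} with elements
#'   \code{m}, \code{V}, \code{Z} (M x (M-1) projections), \code{d},
#'   \code{c}, \code{b} (unnormalized axis), \code{b_hat} (unit axis),
#'   \code{a} (intercept), and \code{layout} (carried from \code{obs}).
#' @seealso [predict.roldsis_fit()], [project_observation()]
#' @examples
#' obs <- observation_set(matrix(rnorm(5 * 128), 5, 128),
#'                        c(0, 0.05, 0.5, 0.95, 1))
#' fit <- roldsis(obs)
#' max(abs(obs$y - predict(fit, obs$X)))  # ~ 0: exact interpolation
#' @export
roldsis <- function(obs, rtol = 1e-10) {
  if (!inherits(obs, "observation_set"))
    obs <- observation_set(obs$X, obs$y, obs$layout)
  X <- obs$X
  y <- obs$y
  bas <- spanned_basis(X, rtol = rtol)
  m <- bas$m
  V <- bas$V
  Xc <- sweep(X, 2L, m)
  Z <- Xc %*% V                       # M x (M-1), z_i in rows
  A <- cbind(1, Z)                    # M x M system  y = c + d'z
  sol <- tryCatch(solve(A, y),
                  error = function(e)
                    stop("roldsis: singular M x M system: ",
                         conditionMessage(e)))
  cc <- sol[1L]
  d <- sol[-1L]
  b <- drop(V %*% d)
  a <- cc - sum(d * drop(crossprod(V, m)))
  nb <- sqrt(sum(b^2))
  if (nb == 0)
    stop("roldsis: degenerate fit (all attributes equal yields b = 0)")
  structure(list(m = m, V = V, Z = Z, d = d, c = cc,
                 b = b, b_hat = b / nb, a = a,
                 layout = obs$layout),
            class = "roldsis_fit")
}

#' @export
print.roldsis_fit <- function(x, ...) {
  cat("RoLDSIS fit: N =", length(x$b), "features, M =", nrow(x$Z),
      "observations\n")
  cat("  intercept a =", signif(x$a, 6),
      " |b| =", signif(sqrt(sum(x$b^2)), 6), "\n")
  invisible(x)
}

#' Predict attributes for new feature vectors
#'
#' Evaluates the fitted affine functional a + b'x.
#'
#' @param object a \code{roldsis_fit}.
#' @param newdata numeric vector of length N, or a matrix with N columns
#'   (one prediction per row).
#' @param ... unused.
#' @return Numeric vector of predicted attribute values.
#' @export
predict.roldsis_fit <- function(object, newdata, ...) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (ncol(newdata) != length(object$b))
    stop("predict.roldsis_fit: newdata has ", ncol(newdata),
         " features, fit expects ", length(object$b))
  drop(object$a + newdata %*% object$b)
}

#' Project an observation onto the fitted axis
#'
#' Returns the representation of \code{x} on the normalized
#' neurophysiological axis: x~ = m + b_hat (b_hat' (x - m)).  The
#' projection is idempotent and x~ - m is parallel to the axis; applied to
#' the training observations, the scalar coordinates b_hat'(x_i - m) are
#' exactly affinely related to the attributes y_i.
#'
#' @param fit a \code{roldsis_fit}.
#' @param x numeric vector of length N, or matrix with N columns (each
#'   row projected separately).
#' @return Object of the same shape as \code{x}.
#' @export
project_observation <- function(fit, x) {
  stopifnot(inherits(fit, "roldsis_fit"))
  vec <- is.vector(x)
  if (vec) x <- matrix(x, nrow = 1L)
  if (ncol(x) != length(fit$b))
    stop("project_observation: x has ", ncol(x),
         " features, fit expects ", length(fit$b))
  xc <- sweep(x, 2L, fit$m)
  coord <- drop(xc %*% fit$b_hat)
  out <- outer(coord, fit$b_hat) + rep(1, length(coord)) %o% fit$m
  if (vec) drop(out) else out
}
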