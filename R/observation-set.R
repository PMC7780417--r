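#' Construct an observation set
#'
#' Bundles M feature vectors (rows of \code{X}) with their scalar stimulus
#' attributes \code{y}.  This is the input of [roldsis()]: in the intended
#' ERP setting each row is the trial-averaged discrete-wavelet feature
#' vector of one stimulus and each attribute is either the physical value
#' of the stimulus (voice onset time, ms) or its psychophysical value
#' (proportion of categorical responses).
#'
#' The regression operates in the HDLSS regime: the number of features N
#' is at least the number of observations M, and the row-centered matrix
#' must have rank M - 1 (observations in "general position").
#'
#' @param X numeric matrix, M observations x N features.
#' @param y numeric vector of length M, one scalar attribute per row.
#' @param layout optional [wavelet_layout()] describing the columns of
#'   \code{X}; carried along so fitted axes can be rendered as scalograms.
#' @return An object of class \code{observation_set} with elements
#'   \code{X}, \code{y} and \code{layout}.
#' @examples
#' X <- matrix(rnorm(5 * 128), 5, 128)
#' obs <- observation_set(X, c(-52, -35, -22, -8, 16))
#' @export
observation_set <- function(X, y, layout = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (nrow(X) < 2L)
    stop("observation_set: at least 2 observations are required (M >= 2)")
  if (ncol(X) < nrow(X))
    stop("observation_set: HDLSS orientation expected (N >= M); got ",
         nrow(X), " rows and ", ncol(X), " columns")
  if (length(y) != nrow(X))
    stop("observation_set: length(y) [", length(y),
         "] must equal nrow(X) [", nrow(X), "]")
  if (!all(is.finite(X)))
    stop("observation_set: X contains non-finite values")
  if (!all(is.finite(y)))
    stop("observation_set: y contains non-finite values")
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "wavelet_layout"))
    if (layout$n_retained != ncol(X))
      stop("observation_set: layout describes ", layout$n_retained,
           " coefficients but X has ", ncol(X), " columns")
  }
  structure(list(X = X, y = y, layout = layout),
            class = "observation_set")
}

#' @export
print.observation_set <- function(x, ...) {
  cat("Observation set: M =", nrow(x$X), "observations, N =",
      ncol(x$X), "features\n")
  cat("  attributes:", paste(signif(x$y, 4), collapse = ", "), "\n")
  if (!is.null(x$layout))
    cat("  feature layout:", paste(x$layout$bands$label, collapse = " "),
        "\n")
  invisible(x)
}

#' @export
dim.observation_set <- function(x) dim(x$X)
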