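# Orthogonal DWT with the length-8 least-asymmetric (symlet) filter and
# periodic boundary handling.  Implemented here because the classic R
# wavelet packages are not part of this package's dependency footprint;
# the filter bank is small and the periodized pyramid algorithm keeps the
# transform exactly orthogonal (Parseval holds to machine precision).

# Scaling (low-pass) filter of the length-8 least-asymmetric Daubechies
# wavelet ("la8"/sym4).  Sum = sqrt(2), unit energy, even-shift
# orthogonality; these identities are asserted in the test suite.
.sym8_scaling <- c(
  -0.075765714789273325, -0.029635527645998510,
   0.497618667632015450,  0.803738751805916140,
   0.297857795605277360, -0.099219543576847216,
  -0.012603967262037833,  0.032223100604042702)

.sym8_wavelet <- function() {
  h <- .sym8_scaling
  L <- length(h)
  (-1)^(seq_len(L) - 1) * rev(h)          # quadrature mirror filter
}

# one periodized analysis step: x (even length) -> list(approx, detail)
.dwt_step <- function(x) {
  h <- .sym8_scaling
  g <- .sym8_wavelet()
  n <- length(x)
  L <- length(h)
  half <- n %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% n + 1L
  xs <- matrix(x[idx], nrow = half)
  list(approx = drop(xs %*% h), detail = drop(xs %*% g))
}

# inverse of .dwt_step (transpose of the orthogonal analysis operator)
.idwt_step <- function(approx, detail) {
  h <- .sym8_scaling
  g <- .sym8_wavelet()
  L <- length(h)
  half <- length(approx)
  n <- 2L * half
  x <- numeric(n)
  for (k in seq_len(half)) {
    pos <- (2L * (k - 1L) + seq_len(L) - 1L) %% n + 1L
    x[pos] <- x[pos] + approx[k] * h + detail[k] * g
  }
  x
}

#' Band structure of a retained DWT coefficient set
#'
#' Describes the dyadic layout of a level-\code{level} DWT of an
#' \code{S}-sample epoch at sampling rate \code{fs}, keeping the
#' approximation block and every detail block entirely below
#' \code{retain_hz}.  Blocks are ordered approximation first ("V8" for an
#' 8-level transform, spanning 0 to fs/2^(level+1) Hz), then detail blocks
#' in increasing frequency ("W8", "W7", ...), detail level l spanning
#' fs/2^(l+1) to fs/2^l Hz.  Each coefficient at level l has a nominal
#' time support of 2^l / fs seconds.
#'
#' With the defaults of the ERP pipeline (S = 2048, fs = 5000 Hz,
#' level = 8, retain_hz = 156.25) the retained blocks are V8, W8, W7, W6,
#' W5 with counts 8, 8, 16, 32, 64 — a feature vector of length 128
#' covering 0–156.25 Hz.
#'
#' @param S epoch length in samples; must be divisible by 2^level.
#' @param fs sampling rate, Hz.
#' @param level decomposition depth.
#' @param retain_hz upper frequency of the retained range; must equal a
#'   dyadic band edge fs/2^j.
#' @return An object of class \code{wavelet_layout}: a list with
#'   \code{bands} (data.frame: label, level, low_hz, high_hz, count,
#'   dt_s), \code{n_retained}, \code{S}, \code{fs}, \code{level}.
#' @export
wavelet_layout <- function(S, fs, level = 8L, retain_hz = fs / 2^5) {
  level <- as.integer(level)
  if (S %% 2L^level != 0L)
    stop("wavelet_layout: S = ", S, " is not divisible by 2^", level)
  if (fs <= 0) stop("wavelet_layout: fs must be positive")
  edges <- fs / 2^(0:(level + 1L))
  if (!any(abs(retain_hz - edges) < 1e-9 * fs))
    stop("wavelet_layout: retain_hz = ", retain_hz,
         " is not a dyadic band edge fs/2^j")
  # approximation block: 0 .. fs/2^(level+1)
  bands <- data.frame(
    label = paste0("V", level),
    level = level,
    low_hz = 0,
    high_hz = fs / 2^(level + 1L),
    count = as.integer(S / 2^level),
    dt_s = 2^level / fs,
    stringsAsFactors = FALSE)
  for (l in seq(level, 1L)) {        # detail levels, increasing frequency
    high <- fs / 2^l
    if (high > retain_hz + 1e-9 * fs) break
    bands <- rbind(bands, data.frame(
      label = paste0("W", l),
      level = l,
      low_hz = fs / 2^(l + 1L),
      high_hz = high,
      count = as.integer(S / 2^l),
      dt_s = 2^l / fs,
      stringsAsFactors = FALSE))
  }
  structure(list(bands = bands,
                 n_retained = as.integer(sum(bands$count)),
                 S = as.integer(S), fs = fs, level = level,
                 retain_hz = retain_hz),
            class = "wavelet_layout")
}

#' @export
print.wavelet_layout <- function(x, ...) {
  cat("Wavelet layout: level-", x$level, " DWT of ", x$S, " samples at ",
      x$fs, " Hz; ", x$n_retained, " retained coefficients\n", sep = "")
  b <- x$bands
  cat(sprintf("  %s: %s-%s Hz (%d coefficients)\n", b$label,
              signif(b$low_hz, 3), signif(b$high_hz, 3), b$count),
      sep = "")
  invisible(x)
}

# full pyramid to `level`; returns list of coefficient blocks, lowest
# frequency first: approx, detail level, level-1, ..., 1
.dwt_pyramid <- function(x, level) {
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    st <- .dwt_step(a)
    a <- st$approx
    details[[l]] <- st$detail        # detail of level l
  }
  c(list(a), rev(details))           # approx, W_level, ..., W_1
}

#' Decompose a signal into retained DWT features
#'
#' Applies the level-\code{level} orthogonal DWT (length-8 symlet,
#' periodic boundaries) and keeps the approximation block plus all detail
#' blocks entirely below \code{retain_hz}, concatenated lowest frequency
#' first.
#'
#' @param signal numeric vector; length must be divisible by 2^level.
#' @param fs sampling rate, Hz.
#' @inheritParams wavelet_layout
#' @return An object of class \code{feature_vector}: list with
#'   \code{values} (retained coefficients) and \code{layout}.
#' @examples
#' fv <- dwt_decompose(sin(2 * pi * 5 * (0:2047) / 5000), fs = 5000)
#' length(fv$values)  # 128
#' @export
dwt_decompose <- function(signal, fs, level = 8L, retain_hz = fs / 2^5) {
  layout <- wavelet_layout(length(signal), fs, level, retain_hz)
  blocks <- .dwt_pyramid(as.numeric(signal), layout$level)
  keep <- seq_len(nrow(layout$bands))
  structure(list(values = unlist(blocks[keep], use.names = FALSE),
                 layout = layout),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("DWT feature vector:", length(x$values), "coefficients (",
      paste(x$layout$bands$label, collapse = " "), ")\n")
  invisible(x)
}

#' Construct a feature vector from raw coefficient values
#'
#' Wraps an existing numeric vector (for example a fitted
#' neurophysiological axis) in the feature-vector container so that
#' [dwt_reconstruct()] and [scalogram()] apply to it.
#'
#' @param values numeric vector whose length equals
#'   \code{layout$n_retained}.
#' @param layout a [wavelet_layout()].
#' @export
feature_vector <- function(values, layout) {
  stopifnot(inherits(layout, "wavelet_layout"))
  values <- as.numeric(values)
  if (length(values) != layout$n_retained)
    stop("feature_vector: expected ", layout$n_retained,
         " values, got ", length(values))
  structure(list(values = values, layout = layout),
            class = "feature_vector")
}

#' Inverse DWT of a retained feature vector
#'
#' Reconstructs the time-domain signal, with every non-retained (high
#' frequency) coefficient set to zero.  A decomposition of a signal that
#' is band-limited below the retention edge round-trips to the original.
#'
#' @param features a \code{feature_vector}.
#' @param total_length target signal length; defaults to the layout's S
#'   and must match it.
#' @return Numeric vector of length \code{total_length}.
#' @export
dwt_reconstruct <- function(features, total_length = NULL) {
  stopifnot(inherits(features, "feature_vector"))
  layout <- features$layout
  if (is.null(total_length)) total_length <- layout$S
  if (total_length != layout$S)
    stop("dwt_reconstruct: layout describes ", layout$S,
         " samples, asked for ", total_length)
  b <- layout$bands
  splits <- rep(seq_len(nrow(b)), b$count)
  blocks <- split(features$values, splits)
  a <- blocks[[1L]]
  # climb back up: retained details first, then zero blocks
  lev <- layout$level
  i <- 2L
  for (l in seq(lev, 1L)) {
    if (i <= nrow(b) && b$level[i] == l && startsWith(b$label[i], "W")) {
      d <- blocks[[i]]
      i <- i + 1L
    } else {
      d <- numeric(length(a))
    }
    a <- .idwt_step(a, d)
  }
  a
}

#' Time-frequency scalogram cells of a feature vector
#'
#' Tiles the time-frequency plane with one cell per retained DWT
#' coefficient: band label, frequency interval, time interval, and the
#' signed coefficient value.  Cell widths double with each coarser level
#' (2^l / fs seconds at detail level l).  Suitable for tile plots where
#' color encodes sign and saturation encodes magnitude.
#'
#' @param features a \code{feature_vector}.
#' @return data.frame with columns \code{band}, \code{low_hz},
#'   \code{high_hz}, \code{t_start}, \code{t_end}, \code{value}.
#' @export
scalogram <- function(features) {
  stopifnot(inherits(features, "feature_vector"))
  b <- features$layout$bands
  out <- do.call(rbind, lapply(seq_len(nrow(b)), function(i) {
    k <- seq_len(b$count[i]) - 1L
    data.frame(band = b$label[i],
               low_hz = b$low_hz[i], high_hz = b$high_hz[i],
               t_start = k * b$dt_s[i],
               t_end = (k + 1L) * b$dt_s[i],
               stringsAsFactors = FALSE)
  }))
  out$value <- features$values
  out
}
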