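# Shared fixture builders.  Everything is generated in code under fixed
# seeds; no data files are shipped.

# random HDLSS observation set with well-conditioned rows
random_obs <- function(M, N, seed = 1L, y = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(M * N), M, N)
  if (is.null(y)) y <- rnorm(M)
  observation_set(X, y)
}

# independent oracle for the minimum-norm exact solution
pinv_axis <- function(X, y) {
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  drop(MASS::ginv(Xc) %*% yc)
}

# circularly periodic sinusoid: k full cycles over S samples
periodic_tone <- function(k, S = 2048L) sin(2 * pi * k * (0:(S - 1L)) / S)

# per-band energies of a feature vector
band_energies <- function(fv) {
  b <- fv$layout$bands
  tapply(fv$values^2, rep(seq_len(nrow(b)), b$count), sum)
}
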