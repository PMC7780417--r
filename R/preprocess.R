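#' Construct an epoched single-channel recording
#'
#' Holds the raw material of one stimulus condition: T stimulus-locked
#' trials of S samples each, the sampling rate and the duration of the
#' pre-stimulus baseline window at the start of every epoch.
#'
#' @param trials numeric matrix, trials x samples (microvolts).
#' @param fs sampling rate, Hz.
#' @param pre_stimulus_s pre-stimulus baseline duration, seconds (the
#'   ERP pipeline default is 0.15 s).
#' @param stimulus_id optional label.
#' @export
epoched_recording <- function(trials, fs, pre_stimulus_s = 0.15,
                              stimulus_id = NULL) {
  trials <- as.matrix(trials)
  storage.mode(trials) <- "double"
  if (nrow(trials) < 1L) stop("epoched_recording: no trials")
  if (fs <= 0) stop("epoched_recording: fs must be positive")
  if (pre_stimulus_s * fs < 1)
    stop("epoched_recording: pre-stimulus window shorter than one sample")
  structure(list(trials = trials, fs = fs,
                 pre_stimulus_s = pre_stimulus_s,
                 stimulus_id = stimulus_id),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat("Epoched recording", if (!is.null(x$stimulus_id))
    paste0("[", x$stimulus_id, "]") else "", ": ",
    nrow(x$trials), " trials x ", ncol(x$trials), " samples at ",
    x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' Baseline-correct each trial
#'
#' Subtracts, per trial, the mean over the pre-stimulus window from the
#' entire epoch, so that every returned trial has zero pre-stimulus mean.
#' Idempotent.
#'
#' @param rec an [epoched_recording()].
#' @return The corrected recording.
#' @export
baseline_correct <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  nb <- floor(rec$pre_stimulus_s * rec$fs)
  if (nb < 1L) stop("baseline_correct: empty pre-stimulus window")
  base <- rowMeans(rec$trials[, seq_len(nb), drop = FALSE])
  rec$trials <- rec$trials - base
  rec
}

#' Reject trials by amplitude threshold
#'
#' Automated artifact rejection: a trial is dropped when its peak absolute
#' amplitude exceeds the threshold.  The default threshold is 5 times the
#' median per-trial peak, a surrogate for manual inspection of
#' excessively noisy epochs.
#'
#' @param rec an [epoched_recording()].
#' @param amplitude_threshold positive scalar, microvolts; \code{NULL}
#'   selects the default.
#' @return List with the filtered recording (\code{recording}) and the
#'   fraction of trials kept (\code{kept_fraction}).
#' @export
reject_trials <- function(rec, amplitude_threshold = NULL) {
  stopifnot(inherits(rec, "epoched_recording"))
  peaks <- apply(abs(rec$trials), 1L, max)
  if (is.null(amplitude_threshold))
    amplitude_threshold <- 5 * stats::median(peaks)
  if (amplitude_threshold <= 0)
    stop("reject_trials: threshold must be positive")
  keep <- peaks <= amplitude_threshold
  if (!any(keep))
    stop("reject_trials: all ", length(keep), " trials exceed threshold ",
         amplitude_threshold)
  rec$trials <- rec$trials[keep, , drop = FALSE]
  list(recording = rec, kept_fraction = mean(keep))
}

#' Average trials into an ERP
#'
#' Sample-wise mean across trials.  Averaging n trials of uncorrelated
#' noise improves the signal-to-noise ratio by 10 log10(n) dB; because
#' the DWT is linear, averaging before or after decomposition is
#' equivalent.
#'
#' @param rec an [epoched_recording()].
#' @return Numeric vector of length S (the ERP).
#' @export
average_trials <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  colMeans(rec$trials)
}

#' Estimate the single-trial signal-to-noise ratio
#'
#' One simple ERP-based estimator: the ERP (trial average) is taken as
#' the signal and each trial's deviation from it as noise, giving
#' SNR = 10 log10(var(ERP) / mean per-trial variance of the deviations).
#' With few trials the ERP itself retains residual noise, so the
#' estimate is biased upward at small T; it is intended as a coarse
#' diagnostic of raw-trial quality (typical auditory ERP recordings sit
#' near -12 to -15 dB).
#'
#' @param rec an [epoched_recording()] with at least 2 trials.
#' @return SNR in dB; \code{Inf} for noiseless (identical) trials.
#' @export
estimate_snr <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (nrow(rec$trials) < 2L)
    stop("estimate_snr: need at least 2 trials")
  erp <- colMeans(rec$trials)
  resid <- sweep(rec$trials, 2L, erp)
  noise <- mean(apply(resid, 1L, stats::var))
  if (noise == 0) return(Inf)
  10 * log10(stats::var(erp) / noise)
}
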