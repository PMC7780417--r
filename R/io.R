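# Delimited/JSON readers and writers shared by the pipeline.  All files
# are plain text: CSV with a header for matrices, JSON for fitted
# objects and configuration sidecars.  Every JSON document carries a
# schema_version stamp.

.schema_version <- "1.0"

#' Write / read an observation set as delimited text
#'
#' The feature matrix goes to a CSV with a header row of feature
#' identifiers (one row per observation); the attributes go to a
#' one-column CSV.
#'
#' @param obs an [observation_set()].
#' @param matrix_file,attr_file file paths.
#' @return \code{write_observation_set} invisibly returns the paths;
#'   \code{read_observation_set} returns an \code{observation_set}.
#' @export
write_observation_set <- function(obs, matrix_file, attr_file) {
  stopifnot(inherits(obs, "observation_set"))
  X <- obs$X
  colnames(X) <- if (!is.null(colnames(obs$X)) &&
                     !all(colnames(obs$X) == "")) colnames(obs$X)
                 else sprintf("f%03d", seq_len(ncol(X)))
  utils::write.csv(X, matrix_file, row.names = FALSE)
  utils::write.csv(data.frame(y = obs$y), attr_file, row.names = FALSE)
  invisible(c(matrix_file, attr_file))
}

#' @rdname write_observation_set
#' @export
read_observation_set <- function(matrix_file, attr_file) {
  X <- as.matrix(utils::read.csv(matrix_file, check.names = FALSE))
  y <- utils::read.csv(attr_file)[[1L]]
  observation_set(X, y)
}

#' Serialize a fitted axis to JSON
#'
#' Writes the scalars and vectors of a \code{roldsis_fit} (or reads them
#' back) with a schema-version field.
#'
#' @param fit a \code{roldsis_fit}.
#' @param path output file.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "roldsis_fit"))
  obj <- list(schema_version = .schema_version,
              type = "roldsis_fit",
              a = fit$a, c = fit$c, d = fit$d,
              b = fit$b, b_hat = fit$b_hat, m = fit$m)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version))
    stop("read_fit_json: missing schema_version in ", path)
  obj
}

#' Write epoched trials with a JSON sidecar
#'
#' One CSV per stimulus (rows = trials, columns = samples or features)
#' plus a sidecar JSON holding the sampling rate, the pre-stimulus
#' window, the stimulus labels and the attribute tables.
#'
#' @param trials list of matrices, one per stimulus.
#' @param dir output directory (created if missing).
#' @param fs sampling rate, Hz.
#' @param pre_stimulus_s baseline window, seconds.
#' @param phi,psi optional attribute vectors, one value per stimulus.
#' @return Invisibly, the sidecar path.
#' @export
write_trials <- function(trials, dir, fs, pre_stimulus_s = 0.15,
                         phi = NULL, psi = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- sprintf("stim%d", seq_along(trials))
  files <- file.path(dir, paste0(labels, ".csv"))
  for (i in seq_along(trials)) {
    M <- as.matrix(trials[[i]])
    colnames(M) <- sprintf("s%04d", seq_len(ncol(M)))
    utils::write.csv(M, files[i], row.names = FALSE)
  }
  sidecar <- list(schema_version = .schema_version,
                  fs = fs, pre_stimulus_s = pre_stimulus_s,
                  stimuli = labels, files = basename(files),
                  phi = phi, psi = psi)
  path <- file.path(dir, "experiment.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read epoched trials written by [write_trials()]
#'
#' @param dir directory containing \code{experiment.json} and the
#'   per-stimulus CSV matrices.
#' @return List with \code{trials} (list of matrices), \code{fs},
#'   \code{pre_stimulus_s}, \code{phi}, \code{psi}.
#' @export
read_trials <- function(dir) {
  path <- file.path(dir, "experiment.json")
  if (!file.exists(path)) stop("read_trials: no experiment.json in ", dir)
  side <- jsonlite::read_json(path, simplifyVector = TRUE)
  trials <- lapply(file.path(dir, side$files), function(f) {
    if (!file.exists(f)) stop("read_trials: missing trial matrix ", f)
    as.matrix(utils::read.csv(f))
  })
  names(trials) <- side$stimuli
  list(trials = trials, fs = side$fs,
       pre_stimulus_s = side$pre_stimulus_s,
       phi = side$phi, psi = side$psi)
}

#' Write a scalogram as a delimited long-format table
#'
#' @param scal data.frame from [scalogram()].
#' @param path output CSV path.
#' @export
write_scalogram <- function(scal, path) {
  utils::write.csv(scal, path, row.names = FALSE)
  invisible(path)
}
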