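#' Multi-sweep voltage-clamp recording
#'
#' Container for a current recording: an ordered list of equal-length sweeps
#' (numeric vectors in pA), the sampling rate and the sweep duration.
#' Indexing is zero-based in all user-facing tables to mirror the original
#' acquisition convention: sample `j` of sweep `i` occurs at absolute time
#' `i * sweep_duration_s + j / sampling_rate_hz` seconds.
#'
#' @param sweeps List of equal-length numeric vectors, one per sweep, in pA.
#' @param sampling_rate_hz Sampling rate in samples/s.
#' @param sweep_duration_s Duration of one sweep in seconds. Each sweep must
#'   hold `round(sampling_rate_hz * sweep_duration_s)` samples.
#' @param source_path Optional provenance path.
#' @param unit_original Unit the samples were stored in on disk ("pA" or "A").
#' @return A `psc_recording` object.
#' @export
psc_recording <- function(sweeps, sampling_rate_hz, sweep_duration_s,
                          source_path = NA_character_, unit_original = "pA") {
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar_number(sweep_duration_s, "sweep_duration_s", positive = TRUE)
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop_format("'sweeps' must be a non-empty list of numeric vectors")
  n_expect <- round(sampling_rate_hz * sweep_duration_s)
  lens <- vapply(sweeps, length, integer(1))
  if (any(lens != n_expect))
    stop_format(sprintf(
      "every sweep must have round(rate * duration) = %d samples; got lengths %s",
      n_expect, paste(unique(lens), collapse = ", ")))
  for (s in sweeps) {
    if (!is.numeric(s) || anyNA(s) || any(!is.finite(s)))
      stop_format("sweep samples must be finite numbers")
  }
  structure(
    list(sampling_rate_hz = sampling_rate_hz,
         sweep_duration_s = sweep_duration_s,
         sweeps = lapply(sweeps, as.numeric),
         source_path = source_path,
         unit_original = match.arg(unit_original, c("pA", "A"))),
    class = "psc_recording")
}

#' @export
print.psc_recording <- function(x, ...) {
  cat(sprintf("<psc_recording> %d sweep(s) x %d samples @ %g Hz (%g s each)\n",
              length(x$sweeps), length(x$sweeps[[1]]),
              x$sampling_rate_hz, x$sweep_duration_s))
  if (!is.na(x$source_path)) cat("  source:", x$source_path, "\n")
  invisible(x)
}

#' Number of sweeps in a recording
#' @param recording A [psc_recording()].
#' @return Integer sweep count.
#' @export
n_sweeps <- function(recording) length(recording$sweeps)

#' Absolute time of a sample
#'
#' @param recording A [psc_recording()].
#' @param sweep_index Zero-based sweep index.
#' @param sample_index Zero-based sample index within the sweep.
#' @return Time in seconds from the start of the recording.
#' @export
sample_time <- function(recording, sweep_index, sample_index) {
  sweep_index * recording$sweep_duration_s +
    sample_index / recording$sampling_rate_hz
}

#' Read a tab-delimited text recording
#'
#' The on-disk format is a headerless tab-delimited rectangle with sweeps
#' organised column-wise; stored values are in A or pA. Values stored in A
#' are converted to pA (exactly x 1e12); pA passes through unchanged.
#'
#' @param path File path.
#' @param sampling_rate_hz Sampling rate the file was acquired at (samples/s).
#' @param sweep_duration_s Duration of one sweep (s). Must satisfy
#'   `round(sampling_rate_hz * sweep_duration_s) ==` rows of the file.
#' @param unit `"pA"` or `"A"`.
#' @return A [psc_recording()]; column k of the file becomes sweep k.
#' @export
read_text_recording <- function(path, sampling_rate_hz, sweep_duration_s,
                                unit = c("pA", "A")) {
  unit <- match.arg(unit)
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar_number(sweep_duration_s, "sweep_duration_s", positive = TRUE)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)          # accept \r\n
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop_format(sprintf("empty recording file: %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- length(fields[[1]])
  bad <- which(vapply(fields, length, integer(1)) != ncol)
  if (length(bad))
    stop_format(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                        path, bad[1], length(fields[[bad[1]]]), ncol))
  mat <- suppressWarnings(
    matrix(as.numeric(unlist(fields)), nrow = length(lines), ncol = ncol,
           byrow = TRUE))
  if (anyNA(mat)) {
    idx <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop_format(sprintf("non-numeric value in %s at line %d, column %d",
                        path, idx[1], idx[2]))
  }
  if (unit == "A") mat <- mat * 1e12
  n_expect <- round(sampling_rate_hz * sweep_duration_s)
  if (nrow(mat) != n_expect)
    stop_format(sprintf(
      "%s has %d samples per sweep but rate x duration gives %d",
      path, nrow(mat), n_expect))
  psc_recording(lapply(seq_len(ncol), function(k) mat[, k]),
                sampling_rate_hz, sweep_duration_s,
                source_path = path, unit_original = unit)
}

#' Write a recording as tab-delimited text
#'
#' Inverse of [read_text_recording()]: sweeps column-wise, no header,
#' values in pA, `\n` line endings.
#'
#' @param recording A [psc_recording()].
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
write_text_recording <- function(recording, path) {
  mat <- do.call(cbind, recording$sweeps)
  lines <- do.call(paste, c(lapply(seq_len(ncol(mat)), function(k)
    sprintf("%.15g", mat[, k])), sep = "\t"))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Import an episodic binary recording (ABF / HEKA DAT)
#'
#' Vendor binary formats are not parsed by this package: no episodic-format
#' reader is available to delegate to, and the supported interchange contract
#' is the tab-delimited text format. Export sweeps to text (most acquisition
#' suites can) and use [read_text_recording()]. This function always refuses
#' with that guidance rather than silently truncating.
#'
#' @param path Path to an ABF or bundled DAT file.
#' @return Never returns.
#' @export
read_episodic_recording <- function(path) {
  stop_format(paste0(
    "episodic binary import (ABF/DAT) is not supported in this build: ",
    "export the series as tab-delimited text (sweeps column-wise, unit A or pA, ",
    "recommended sampling rate 10-20 kHz) and use read_text_recording()"))
}
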