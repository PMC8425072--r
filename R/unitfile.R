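#' Per-cell event list ("unit file" record)
#'
#' A unit record is the persisted result of event detection for one cell:
#' an ordered table of events with absolute peak time (s), amplitude (pA)
#' and a 0/1 selection index marking the contiguous block of events chosen
#' for downstream statistics.
#'
#' @param name Base name of the unit (file name without extension).
#' @param events Data frame with columns `time_s` (strictly increasing),
#'   `amplitude_pa` (>= 0) and `selected` (0 or 1). May have zero rows.
#' @return A `unit_record` object.
#' @export
unit_record <- function(name, events) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop_format("'name' must be a non-empty string")
  events <- as.data.frame(events)
  need <- c("time_s", "amplitude_pa", "selected")
  if (!all(need %in% names(events)))
    stop_format(paste("events must have columns", paste(need, collapse = ", ")))
  events <- events[need]
  if (nrow(events)) {
    if (anyNA(events) || !all(vapply(events, is.numeric, logical(1))))
      stop_format(sprintf("unit '%s': event fields must be numeric and non-missing", name))
    if (any(diff(events$time_s) <= 0))
      stop_format(sprintf("unit '%s': event times must be strictly increasing", name))
    if (!all(events$selected %in% c(0, 1)))
      stop_format(sprintf("unit '%s': selection index must be 0 or 1", name))
    if (any(events$amplitude_pa < 0))
      stop_format(sprintf("unit '%s': amplitudes must be >= 0", name))
    events$selected <- as.integer(events$selected)
  }
  rownames(events) <- NULL
  structure(list(name = name, events = events), class = "unit_record")
}

#' @export
print.unit_record <- function(x, ...) {
  n <- nrow(x$events)
  cat(sprintf("<unit_record> '%s': %d event(s), %d selected\n",
              x$name, n, if (n) sum(x$events$selected) else 0L))
  invisible(x)
}

#' Write a unit file
#'
#' Tab-delimited text, no header, one line per event with three fields:
#' absolute event time (s), amplitude (pA), selection index (0/1). An empty
#' record produces an empty file. Numbers are written with up to 15
#' significant digits so that [read_unit_file()] round-trips within text
#' float precision.
#'
#' @param record A [unit_record()].
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
write_unit_file <- function(record, path) {
  stopifnot(inherits(record, "unit_record"))
  ev <- record$events
  lines <- if (nrow(ev)) {
    paste(sprintf("%.15g", ev$time_s),
          sprintf("%.15g", ev$amplitude_pa),
          sprintf("%d", ev$selected), sep = "\t")
  } else character(0)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

#' Read a unit file
#'
#' @param path Path to a 3-column tab-delimited unit file (see
#'   [write_unit_file()]). Plain decimal and scientific notation are both
#'   accepted; `\n` and `\r\n` line endings are accepted.
#' @return A [unit_record()] named after the file's base name.
#' @export
read_unit_file <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  name <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(unit_record(name, data.frame(time_s = numeric(0),
                                        amplitude_pa = numeric(0),
                                        selected = integer(0))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 3L)
  if (length(bad))
    stop_format(sprintf("%s: line %d has %d fields, expected 3 (time, amplitude, selection)",
                        path, bad[1], length(fields[[bad[1]]])))
  mat <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 3, byrow = TRUE))
  if (anyNA(mat))
    stop_format(sprintf("%s: non-numeric value on line %d",
                        path, which(rowSums(is.na(mat)) > 0)[1]))
  unit_record(name, data.frame(time_s = mat[, 1], amplitude_pa = mat[, 2],
                               selected = mat[, 3]))
}

#' Write the pooled "whole data" table for a retrieval
#'
#' Concatenates the events of several unit records into one tab-delimited
#' file with a single header line and five fields per event: time (s),
#' amplitude (pA), selection index, unit file name, and the search pattern
#' that retrieved the unit. Intended for further analysis in third-party
#' tools.
#'
#' @param records Non-empty list of [unit_record()]s.
#' @param patterns Character vector of search patterns, one per record
#'   (recycled if length 1).
#' @param path Output path.
#' @return `invisible(path)`.
#' @export
write_whole_data <- function(records, patterns, path) {
  if (!is.list(records) || length(records) == 0L)
    stop_format("'records' must be a non-empty list of unit records")
  patterns <- rep_len(as.character(patterns), length(records))
  header <- paste("time_s", "amplitude_pa", "selected",
                  "unit_file_name", "search_pattern", sep = "\t")
  body <- unlist(lapply(seq_along(records), function(i) {
    r <- records[[i]]
    stopifnot(inherits(r, "unit_record"))
    ev <- r$events
    if (!nrow(ev)) return(character(0))
    paste(sprintf("%.15g", ev$time_s), sprintf("%.15g", ev$amplitude_pa),
          sprintf("%d", ev$selected), r$name, patterns[i], sep = "\t")
  }))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}
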