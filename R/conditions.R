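# Structured error conditions so the CLI can map failures to exit codes:
# usage errors (2), format/validation errors (3), numeric failures (4).

stop_usage <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("psc_usage_error", "psc_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("psc_format_error", "psc_error")))
}

stop_numeric <- function(msg) {
  stop(errorCondition(msg, class = c("psc_numeric_error", "psc_error")))
}

check_scalar_number <- function(x, name, positive = FALSE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_format(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0)
    stop_format(sprintf("'%s' must be positive (got %g)", name, x))
  if (integer && x != round(x))
    stop_format(sprintf("'%s' must be an integer (got %g)", name, x))
  invisible(x)
}

#' Append a timestamped line to an analysis log
#'
#' Every executed action is recorded as a timestamped plain-text line,
#' appended to `path`, so an analysis can be replayed from its log.
#'
#' @param path Log file path; created if absent. `NULL` is a silent no-op.
#' @param message One-line description of the action.
#' @return `invisible(NULL)`.
#' @export
log_action <- function(path, message) {
  if (is.null(path)) return(invisible(NULL))
  line <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), "\t", message)
  cat(line, "\n", sep = "", file = path, append = TRUE)
  invisible(NULL)
}
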