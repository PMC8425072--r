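# Batch "retriever" layer: wildcard retrieval of unit files, per-unit and
# per-group descriptive statistics, cumulative relative histograms, and the
# three hypothesis tests used to compare groups of cells.

#' Find unit files by wildcard pattern
#'
#' Recursively searches `root` for files whose base name (without extension)
#' matches `pattern`, where `?` matches exactly one character and every other
#' character is literal; matching is case-insensitive. Files lying under any
#' folder whose name appears in `exclude_folders` (case-insensitive, at any
#' depth) are omitted. The result is in deterministic lexicographic order.
#'
#' @param root Directory to search.
#' @param pattern Non-empty pattern, e.g. `"??????_VC_#??"`.
#' @param exclude_folders Character vector of folder names to skip.
#' @return Sorted character vector of file paths.
#' @export
find_unit_files <- function(root, pattern, exclude_folders = character(0)) {
  if (!dir.exists(root)) stop_format(sprintf("directory not found: %s", root))
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop_format("'pattern' must be a non-empty string")
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  if (length(exclude_folders)) {
    rel <- list.files(root, recursive = TRUE, full.names = FALSE)
    parts <- strsplit(rel, "/", fixed = TRUE)
    excl <- tolower(exclude_folders)
    drop <- vapply(parts, function(p)
      length(p) > 1L && any(tolower(p[-length(p)]) %in% excl), logical(1))
    files <- files[!drop]
  }
  rx <- paste0("^", gsub("\\?", ".", escape_regex_keep_qmark(pattern)), "$")
  base <- tools::file_path_sans_ext(basename(files))
  hits <- files[grepl(rx, base, ignore.case = TRUE)]
  sort(hits, method = "radix")
}

# escape regex metacharacters except '?', which is the wildcard
escape_regex_keep_qmark <- function(x) {
  gsub("([^?[:alnum:]])", "\\\\\\1", x)
}

#' Load unit files, tolerating per-file failures
#'
#' Validates and reads each path with [read_unit_file()]. Files that fail
#' validation are reported (one named diagnostic each) and skipped; loading
#' only fails outright when every file is unreadable or the path list is
#' empty. Order is preserved.
#'
#' @param paths Character vector of unit-file paths.
#' @return List with `records` (the loaded [unit_record()]s) and `failures`
#'   (named character vector of per-file error messages).
#' @export
load_units <- function(paths) {
  if (!length(paths)) stop_format("no unit files to load")
  records <- list()
  failures <- character(0)
  for (p in paths) {
    r <- tryCatch(read_unit_file(p), error = function(e) e)
    if (inherits(r, "error")) {
      failures[[p]] <- conditionMessage(r)
    } else {
      records[[length(records) + 1L]] <- r
    }
  }
  if (!length(records))
    stop_format(paste0("all unit files failed to load: ",
                       paste(failures, collapse = "; ")))
  list(records = records, failures = failures)
}

unit_stats <- function(record) {
  ev <- record$events
  sel <- ev[ev$selected == 1L, , drop = FALSE]
  freq <- function(e) if (nrow(e)) nrow(e) / e$time_s[nrow(e)] else NA_real_
  data.frame(
    name = record$name,
    n_total = nrow(ev),
    n_selected = nrow(sel),
    mean_amplitude_t = if (nrow(ev)) mean(ev$amplitude_pa) else NA_real_,
    mean_amplitude_s = if (nrow(sel)) mean(sel$amplitude_pa) else NA_real_,
    frequency_t = freq(ev),
    frequency_s = freq(sel))
}

#' Summarise a group of unit records
#'
#' Per unit: event counts, mean amplitudes and event frequencies for the
#' total (`_t`) and selected (`_s`) events. Frequency is defined as the
#' number of events divided by the time of the last event (the unit file
#' does not persist the recording duration). Group statistics (mean, sample
#' SD and SEM over the per-unit values) exclude missing per-unit values
#' pairwise; `SEM = SD / sqrt(n_units)` with `n_units` the non-missing
#' count.
#'
#' @param records List of [unit_record()]s.
#' @return A `group_summary`: list with `per_unit` and `group` data frames.
#' @export
summarize_group <- function(records) {
  if (!is.list(records) || !length(records))
    stop_format("'records' must be a non-empty list of unit records")
  per_unit <- do.call(rbind, lapply(records, unit_stats))
  rownames(per_unit) <- NULL
  gs <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    c(mean = if (n) mean(v) else NA_real_, sd = s,
      sem = if (n >= 2) s / sqrt(n) else NA_real_, n = n)
  }
  cols <- c("mean_amplitude_t", "mean_amplitude_s", "frequency_t", "frequency_s")
  group <- as.data.frame(t(vapply(cols, function(cn) gs(per_unit[[cn]]),
                                  numeric(4))))
  group <- cbind(measure = cols, group)
  rownames(group) <- NULL
  structure(list(per_unit = per_unit, group = group), class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %d unit(s)\n", nrow(x$per_unit)))
  print(x$group, row.names = FALSE)
  invisible(x)
}

#' Cumulative relative histogram
#'
#' Bins `values` into `n_bins` equal-width bins on `[begin, end]` and
#' returns the cumulative relative frequency at each bin's upper edge.
#' Values below `begin` fall in the first bin and values above `end` in the
#' last (clipping), so the curve is non-decreasing and ends at exactly 1.
#'
#' @param values Non-empty numeric vector (e.g. amplitudes or IEIs).
#' @param n_bins Number of bins (>= 1).
#' @param begin,end Histogram range, `end > begin`.
#' @return Data frame with `bin_upper` and `cum_rel_freq`.
#' @export
cumulative_relative_histogram <- function(values, n_bins, begin, end) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values))
    stop_format("'values' must be non-empty and non-missing")
  check_scalar_number(n_bins, "n_bins", positive = TRUE, integer = TRUE)
  check_scalar_number(begin, "begin")
  check_scalar_number(end, "end")
  if (end <= begin) stop_format("'end' must exceed 'begin'")
  edges <- seq(begin, end, length.out = n_bins + 1L)
  width <- (end - begin) / n_bins
  bin <- pmin(pmax(ceiling((values - begin) / width), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  data.frame(bin_upper = edges[-1L],
             cum_rel_freq = cumsum(counts) / length(values))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the absolute difference between the two empirical
#' cumulative distribution functions; the p-value comes from the asymptotic
#' Kolmogorov distribution with the standard effective-sample-size
#' correction (via [stats::ks.test()] with `exact = FALSE`). Intended for
#' pooled event-level values (amplitudes or IEIs of the selected events)
#' from two groups.
#'
#' @param x,y Numeric samples, each of size >= 2.
#' @return List with `statistic` (D), `p_value`, `n_x`, `n_y`.
#' @export
ks_two_sample <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop_format("both samples must have at least 2 values")
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value),
       n_x = length(x), n_y = length(y))
}

#' Independent two-sample t-test on per-unit means
#'
#' Classic pooled-variance Student's t-test (two-sided); set
#' `var_equal = FALSE` for Welch's variant. When the pooled variance is zero
#' the test degenerates: equal means give `t = 0, p = 1`; unequal means give
#' an infinite t with `p = 0`.
#'
#' @param a,b Numeric vectors of per-unit values, each of size >= 2.
#' @param var_equal Pool the variances (default `TRUE`).
#' @return List with `t`, `df`, `p_value`.
#' @export
t_test_independent <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop_format("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1))
    return(list(t = sign(mean(a) - mean(b)) * Inf,
                df = length(a) + length(b) - 2, p_value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value))
}

#' One-way ANOVA on per-unit values
#'
#' Standard between/within sum-of-squares decomposition across two or more
#' groups. With exactly two groups, `F = t^2` and the p-value equals the
#' pooled-variance t-test's. Degenerate inputs (zero within-group variance)
#' are guarded as in [t_test_independent()].
#'
#' @param groups List of >= 2 numeric vectors, each of size >= 2.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop_format("'groups' must be a list of at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop_format("each group needs at least 2 values")
  vals <- unlist(groups)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  df1 <- length(groups) - 1L
  df2 <- length(vals) - length(groups)
  gm <- mean(vals)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - gm)^2, numeric(1)))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), numeric(1)))
  if (ss_within == 0) {
    if (ss_between == 0) return(list(F = 0, df1 = df1, df2 = df2, p_value = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p_value = 0))
  }
  a <- stats::anova(stats::lm(vals ~ fac))
  list(F = a[["F value"]][1L], df1 = a[["Df"]][1L], df2 = a[["Df"]][2L],
       p_value = a[["Pr(>F)"]][1L])
}

#' Export retrieval results
#'
#' Writes the group summary as TSV, each cumulative histogram series as TSV,
#' a minimal self-contained HTML page carrying the same histogram series,
#' and the hypothesis-test results as TSV (test, statistic, df, p). Output
#' is deterministic: identical inputs re-export byte-identically.
#'
#' @param summary A [summarize_group()] result (or `NULL` to skip).
#' @param histograms Named list of [cumulative_relative_histogram()] data
#'   frames (or `NULL`).
#' @param tests Data frame with columns `test`, `statistic`, `df`, `p_value`
#'   (or `NULL`).
#' @param out_dir Output directory; created if needed.
#' @return Invisible character vector of the files written.
#' @export
export_results <- function(summary = NULL, histograms = NULL, tests = NULL,
                           out_dir = ".") {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop_format(sprintf("cannot create output directory: %s", out_dir))
  written <- character(0)
  tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    path
  }
  if (!is.null(summary)) {
    written <- c(written, tsv(summary$per_unit, "summary_per_unit.tsv"),
                 tsv(summary$group, "summary_group.tsv"))
  }
  if (!is.null(histograms) && length(histograms)) {
    for (nm in names(histograms))
      written <- c(written, tsv(histograms[[nm]],
                                paste0("histogram_", nm, ".tsv")))
    html <- c("<!DOCTYPE html>", "<html><head><meta charset=\"utf-8\">",
              "<title>Cumulative relative histograms</title></head><body>")
    for (nm in names(histograms)) {
      h <- histograms[[nm]]
      html <- c(html, sprintf("<h2>%s</h2>", nm),
                "<table><tr><th>bin_upper</th><th>cum_rel_freq</th></tr>",
                sprintf("<tr><td>%.15g</td><td>%.15g</td></tr>",
                        h$bin_upper, h$cum_rel_freq),
                "</table>")
    }
    html <- c(html, "</body></html>")
    hpath <- file.path(out_dir, "cumulative_histograms.html")
    writeLines(html, hpath)
    written <- c(written, hpath)
  }
  if (!is.null(tests) && nrow(tests)) {
    written <- c(written, tsv(tests, "hypothesis_tests.tsv"))
  }
  invisible(written)
}

#' Pool event-level values from a group of unit records
#'
#' Convenience for the K-S comparisons: pools amplitudes or inter-event
#' intervals of the selected events (falling back to all events when a unit
#' has no selection) across the group's units.
#'
#' @param records List of [unit_record()]s.
#' @param measure `"amplitude"` or `"iei"`.
#' @param selected_only Use only selected events where a selection exists.
#' @return Numeric vector of pooled values.
#' @export
pool_event_values <- function(records, measure = c("amplitude", "iei"),
                              selected_only = TRUE) {
  measure <- match.arg(measure)
  unlist(lapply(records, function(r) {
    ev <- r$events
    if (selected_only && any(ev$selected == 1L))
      ev <- ev[ev$selected == 1L, , drop = FALSE]
    if (measure == "amplitude") ev$amplitude_pa
    else if (nrow(ev) >= 2) diff(ev$time_s) else numeric(0)
  }))
}
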