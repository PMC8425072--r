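# Detector scoring against simulation ground truth: one-to-one greedy
# matching of peak times, confusion matrix, precision/recall/F1, and the
# smoothing-parameter sweep harness.

#' Match detected events to ground truth
#'
#' One-to-one greedy matching by ascending absolute peak-time difference
#' within `tolerance_ms`: matched pairs are true positives, unmatched
#' detections false positives, unmatched truth events false negatives.
#' True negatives are the count of `segment_s`-long grid segments containing
#' neither a true nor a detected peak; they are reported but play no role in
#' precision, recall or F1.
#'
#' @param detected A `psc_events` object or numeric vector of detected peak
#'   times (s).
#' @param truth Truth data frame from [simulate_recording()] (or a numeric
#'   vector of true peak times in s).
#' @param tolerance_ms Matching tolerance in ms (default 5).
#' @param duration_s Recording duration used for the TN segment grid;
#'   defaults to the ceiling of the last peak time.
#' @param segment_s TN grid segment length (default 1 s).
#' @return A `confusion_matrix` object with fields `tp`, `tn`, `fp`, `fn`,
#'   plus the matched pair table in `$pairs`.
#' @export
match_events <- function(detected, truth, tolerance_ms = 5,
                         duration_s = NULL, segment_s = 1) {
  check_scalar_number(tolerance_ms, "tolerance_ms", positive = TRUE)
  det <- if (inherits(detected, "psc_events")) detected$events$peak_time_s
         else as.numeric(detected)
  tru <- if (is.data.frame(truth)) truth$peak_time_s else as.numeric(truth)
  det <- sort(det)
  tru_sorted <- sort(tru)
  tol <- tolerance_ms / 1000
  # candidate pairs: for each detection, truths within the tolerance
  pairs <- NULL
  if (length(det) && length(tru_sorted)) {
    lo <- findInterval(det - tol, tru_sorted) + 1L
    hi <- findInterval(det + tol, tru_sorted)
    keep <- which(lo <= hi)
    if (length(keep)) {
      pairs <- do.call(rbind, lapply(keep, function(i)
        data.frame(det = i, tru = lo[i]:hi[i],
                   dt = abs(det[i] - tru_sorted[lo[i]:hi[i]]))))
      pairs <- pairs[order(pairs$dt, pairs$det, pairs$tru), , drop = FALSE]
    }
  }
  det_matched <- logical(length(det))
  tru_matched <- logical(length(tru_sorted))
  matched <- NULL
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      i <- pairs$det[r]; j <- pairs$tru[r]
      if (!det_matched[i] && !tru_matched[j]) {
        det_matched[i] <- TRUE
        tru_matched[j] <- TRUE
        matched <- rbind(matched, pairs[r, ])
      }
    }
  }
  if (is.null(duration_s))
    duration_s <- ceiling(max(c(det, tru_sorted, segment_s)))
  seg <- unique(c(
    pmin(floor(det / segment_s), ceiling(duration_s / segment_s) - 1),
    pmin(floor(tru_sorted / segment_s), ceiling(duration_s / segment_s) - 1)))
  tn <- ceiling(duration_s / segment_s) - length(seg)
  structure(list(tp = sum(det_matched), tn = as.integer(tn),
                 fp = sum(!det_matched), fn = sum(!tru_matched),
                 tolerance_ms = tolerance_ms, segment_s = segment_s,
                 pairs = matched),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- precision_recall_f1(x)
  cat(sprintf("<confusion_matrix> TP=%d FP=%d FN=%d TN=%d (tolerance %g ms)\n",
              x$tp, x$fp, x$fn, x$tn, x$tolerance_ms))
  cat(sprintf("  precision=%.5g recall=%.5g F1=%.5g\n",
              m["precision"], m["recall"], m["f1"]))
  invisible(x)
}

#' Precision, recall and F1 from a confusion matrix
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`, and F1 is their
#' harmonic mean. When TP = 0 an undefined ratio (zero denominator) is
#' reported as `NA` and F1 as 0.
#'
#' @param cm A [match_events()] result, or any list with `tp`, `fp`, `fn`.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm) {
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (tp > 0) 2 * precision * recall / (precision + recall) else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Sweep smoothing parameters against ground truth
#'
#' Re-runs the full detector over a grid of polynomial orders and side
#' points (and optionally several minimum-amplitude criteria), scoring each
#' setting against the simulation ground truth. Invalid window combinations
#' (`2 * side + 1 <= poly`) are skipped with a message. Within one
#' (poly, side) cell the detection pass is shared across minimum-amplitude
#' values: the criterion only thresholds candidate amplitudes, so the result
#' is identical to a direct [detect()] run at each value.
#'
#' @param noisy_recording The noise-added benchmark [psc_recording()].
#' @param truth Truth table from [simulate_recording()].
#' @param poly_orders Integer vector of polynomial orders (e.g. `c(3, 4)`).
#' @param side_points Integer vector of side-point values (e.g. `2:50`).
#' @param min_amplitude_pa Numeric vector of minimum amplitudes (default 10).
#' @param tolerance_ms Matching tolerance (default 5 ms).
#' @param params Base [detection_params()] supplying the remaining settings.
#' @return Data frame with one row per (poly, side, min amplitude):
#'   counts, precision, recall, f1, `n_detected` and
#'   `mean_detected_amplitude_pa` (over all detected events, `NA` if none).
#' @export
parameter_sweep <- function(noisy_recording, truth, poly_orders = c(3L, 4L),
                            side_points = 2:50, min_amplitude_pa = 10,
                            tolerance_ms = 5, params = detection_params()) {
  stopifnot(inherits(noisy_recording, "psc_recording"))
  rate <- noisy_recording$sampling_rate_hz
  duration <- noisy_recording$sweep_duration_s * n_sweeps(noisy_recording)
  # the trend is estimated from the raw trace, so it is shared by the grid
  trends <- lapply(noisy_recording$sweeps, estimate_trend, rate,
                   params$trend_window_s)
  rows <- list()
  for (po in poly_orders) {
    for (sp in side_points) {
      if (2L * sp + 1L <= po) {
        message(sprintf("skipping poly %d, side %d: window 2x%d+1 <= order",
                        po, sp, sp))
        next
      }
      p <- modify_params(params, poly_order = po, side_points = sp,
                         min_amplitude_pa = min(min_amplitude_pa))
      cand <- lapply(seq_along(noisy_recording$sweeps), function(k) {
        cc <- detect_sweep_candidates(noisy_recording$sweeps[[k]], p, rate,
                                      trend = trends[[k]])
        cc$peak_time_s <- sample_time(noisy_recording, k - 1L, cc$peak_index)
        cc
      })
      cand <- do.call(rbind, cand)
      for (ma in min_amplitude_pa) {
        ev <- apply_min_amplitude(cand, ma, params$amplitude_rule)
        cm <- match_events(ev$peak_time_s, truth, tolerance_ms,
                           duration_s = duration)
        met <- precision_recall_f1(cm)
        rows[[length(rows) + 1L]] <- data.frame(
          poly_order = po, side_points = sp, min_amplitude_pa = ma,
          tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
          precision = met[["precision"]], recall = met[["recall"]],
          f1 = met[["f1"]], n_detected = nrow(ev),
          mean_detected_amplitude_pa =
            if (nrow(ev)) mean(ev$amplitude_pa) else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
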