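#' Event-detection parameters
#'
#' Bundles the four user-facing knobs of the detector plus the fixed internal
#' settings of the search stages.
#'
#' @param polarity Direction of the events: `"negative"` (inward currents,
#'   valleys; the usual EPSC case) or `"positive"`.
#' @param min_amplitude_pa Minimum peak-to-baseline amplitude (pA) an event
#'   must reach in the final search. Default 10.
#' @param poly_order Polynomial order of the Savitzky-Golay smoother.
#'   Higher order smooths less. Default 3.
#' @param side_points Half-window of the smoother: the window spans
#'   `2 * side_points + 1` samples. More side points smooth more. Default 14.
#' @param initial_threshold_pa Deviation from the trend (pA) a local extremum
#'   of the smoothed trace must exceed to become a candidate. Default 3.
#' @param baseline_max_lookback_ms Cap on the backward baseline search, in ms.
#'   Default 10.
#' @param min_separation_ms Minimum spacing between accepted candidates in the
#'   initial search; when two candidates fall closer, the one deviating more
#'   from the trend wins. Default 2.
#' @param trend_window_s Width of the running-median trend window (s).
#'   Default 0.5.
#' @param amplitude_rule `"gte"` retains events with amplitude exactly equal
#'   to `min_amplitude_pa` (the default reading of "exceeding over the
#'   criterion"); `"gt"` drops ties.
#' @param baseline_cap `"trend"` (default) caps the baseline value at the
#'   running-trend estimate so noise excursions above the holding level
#'   cannot inflate event amplitudes; `"none"` uses the smoothed value at
#'   the baseline sample unmodified.
#' @return A `detection_params` object.
#' @export
detection_params <- function(polarity = c("negative", "positive"),
                             min_amplitude_pa = 10,
                             poly_order = 3L,
                             side_points = 14L,
                             initial_threshold_pa = 3,
                             baseline_max_lookback_ms = 10,
                             min_separation_ms = 2,
                             trend_window_s = 0.5,
                             amplitude_rule = c("gte", "gt"),
                             baseline_cap = c("trend", "none")) {
  polarity <- match.arg(polarity)
  amplitude_rule <- match.arg(amplitude_rule)
  baseline_cap <- match.arg(baseline_cap)
  check_scalar_number(min_amplitude_pa, "min_amplitude_pa", positive = TRUE)
  check_scalar_number(poly_order, "poly_order", positive = TRUE, integer = TRUE)
  check_scalar_number(side_points, "side_points", positive = TRUE, integer = TRUE)
  check_scalar_number(initial_threshold_pa, "initial_threshold_pa", positive = TRUE)
  check_scalar_number(baseline_max_lookback_ms, "baseline_max_lookback_ms",
                      positive = TRUE)
  check_scalar_number(min_separation_ms, "min_separation_ms", positive = TRUE)
  check_scalar_number(trend_window_s, "trend_window_s", positive = TRUE)
  if (2L * side_points + 1L <= poly_order)
    stop_format(sprintf(
      "smoothing window (2 x %d + 1) must exceed poly_order %d",
      side_points, poly_order))
  structure(
    list(polarity = polarity,
         min_amplitude_pa = min_amplitude_pa,
         poly_order = as.integer(poly_order),
         side_points = as.integer(side_points),
         initial_threshold_pa = initial_threshold_pa,
         baseline_max_lookback_ms = baseline_max_lookback_ms,
         min_separation_ms = min_separation_ms,
         trend_window_s = trend_window_s,
         amplitude_rule = amplitude_rule,
         baseline_cap = baseline_cap),
    class = "detection_params")
}

#' @export
print.detection_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<detection_params> polarity=%s, min amplitude=%g pA, poly order=%d, ",
    "side points=%d, initial threshold=%g pA\n"),
    x$polarity, x$min_amplitude_pa, x$poly_order, x$side_points,
    x$initial_threshold_pa))
  invisible(x)
}

modify_params <- function(params, ...) {
  upd <- list(...)
  args <- unclass(params)
  args[names(upd)] <- upd
  do.call(detection_params, args)
}
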