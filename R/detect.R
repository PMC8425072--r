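# The stepwise detector: smoothing, initial search against the trend,
# backward baseline search, and amplitude-based final acceptance. All
# stages run on the negative-going orientation internally; positive-going
# events are handled by negating the trace, which makes every stage exactly
# polarity-symmetric.

# Centred running maximum over a window of +/- h samples, computed by
# prefix doubling (O(n log h), all vectorised). Out-of-range positions act
# as -Inf.
window_max <- function(x, h) {
  n <- length(x)
  L <- 2L * h + 1L
  xp <- c(rep(-Inf, h), x, rep(-Inf, h))
  len <- 1L
  while (2L * len <= L) len <- 2L * len
  m <- xp
  s <- 1L
  while (s < len) {
    m <- pmax(m, c(m[-seq_len(s)], rep(-Inf, s)))
    s <- 2L * s
  }
  # m[i] = max xp[i .. i + len - 1]; window for x[j] starts at xp index j
  pmax(m[seq_len(n)], m[seq_len(n) + (L - len)])
}

# Local extrema at the event scale: sample j is a scale-h local maximum when
# it attains the maximum of its +/- h sample window. Two distinct scale-h
# maxima are more than h samples apart unless their values tie exactly, so
# the minimum inter-candidate separation is enforced by construction; exact
# ties within h samples keep the earliest.
scale_local_maxima <- function(x, h) {
  idx <- which(x == window_max(x, h))
  if (length(idx) >= 2L) {
    keep <- c(TRUE, diff(idx) > h)
    # a run of tied indices closer than h collapses to its first member
    idx <- idx[cummax_runs(keep, idx, h)]
  }
  idx
}

cummax_runs <- function(keep, idx, h) {
  last <- idx[1L]
  out <- logical(length(idx))
  out[1L] <- TRUE
  for (k in seq_along(idx)[-1L]) {
    if (idx[k] - last > h) {
      out[k] <- TRUE
      last <- idx[k]
    }
  }
  out
}

#' Initial search: candidate peaks against the trend
#'
#' Finds local extrema of `smoothed - trend` in the polarity direction whose
#' deviation from the trend exceeds `initial_threshold_pa`. Extrema are
#' taken at the detector's event scale: a candidate valley must attain the
#' minimum of its `min_separation_ms`-wide one-sided window, which both
#' ignores sub-scale noise wiggles and enforces the minimum inter-candidate
#' separation (exact ties keep the earliest sample).
#'
#' @param smoothed Smoothed trace (pA).
#' @param trend Trend estimate of the same length (pA).
#' @param polarity `"negative"` or `"positive"`.
#' @param initial_threshold_pa Deviation threshold in pA (default 3).
#' @param sampling_rate_hz Sampling rate, used to convert the separation
#'   window to samples.
#' @param min_separation_ms Extremum scale / minimum candidate spacing
#'   (default 2 ms).
#' @return Strictly increasing zero-based candidate sample indices.
#' @export
initial_search <- function(smoothed, trend, polarity = "negative",
                           initial_threshold_pa = 3,
                           sampling_rate_hz = 10000,
                           min_separation_ms = 2) {
  if (length(smoothed) != length(trend))
    stop_format("'smoothed' and 'trend' must have equal length")
  d <- smoothed - trend
  if (polarity == "positive") d <- -d
  h <- max(1L, round(min_separation_ms / 1000 * sampling_rate_hz))
  idx <- scale_local_maxima(-d, h)
  idx[d[idx] < -initial_threshold_pa] - 1L
}

#' Backward baseline search for one peak
#'
#' Searches backwards from the peak (valley) for the pre-event local
#' extremum of opposite polarity in the smoothed trace: the nearest
#' preceding sample that attains the maximum of its
#' `baseline_scale_ms`-wide one-sided window (for negative-going events;
#' mirrored for positive), i.e. a first-difference sign change at the
#' detector's event scale, confirmed by the scale-h discrete second
#' derivative being <= 0 there (implied by the window-maximum property).
#' The search is capped at `baseline_max_lookback_ms`; if no such point
#' exists in the window the window edge is returned.
#'
#' @param smoothed Smoothed trace (pA).
#' @param peak_index Zero-based peak sample index (must be > 0).
#' @param polarity `"negative"` or `"positive"`.
#' @param baseline_max_lookback_ms Search cap in ms (default 10).
#' @param sampling_rate_hz Sampling rate (samples/s).
#' @param baseline_scale_ms Extremum scale in ms (default 2, matching the
#'   initial search).
#' @param not_before_index Optional zero-based index the search may not
#'   reach past (the previous event's peak), so a secondary dip on a
#'   recovery limb is not measured across the preceding event.
#' @return Zero-based baseline sample index, strictly less than `peak_index`.
#' @export
baseline_search <- function(smoothed, peak_index, polarity = "negative",
                            baseline_max_lookback_ms = 10,
                            sampling_rate_hz = 10000,
                            baseline_scale_ms = 2,
                            not_before_index = NULL) {
  p <- as.integer(peak_index) + 1L   # to 1-based
  n <- length(smoothed)
  if (p < 2L || p > n) stop_format("peak too close to the sweep start for a baseline")
  s <- if (polarity == "positive") -smoothed else smoothed
  L <- max(1L, round(baseline_max_lookback_ms / 1000 * sampling_rate_hz))
  h <- max(1L, round(baseline_scale_ms / 1000 * sampling_rate_hz))
  edge <- max(1L, p - L)
  if (!is.null(not_before_index))
    edge <- max(edge, as.integer(not_before_index) + 2L)
  lo <- max(1L, edge - h)
  hi <- min(n, p + h)
  seg <- s[lo:hi]
  wm <- window_max(seg, h)
  cand <- which(seg == wm) + lo - 1L
  cand <- cand[cand >= edge & cand < p]
  if (length(cand)) max(cand) - 1L else edge - 1L
}

# vectorised baseline search used by the detector: for every peak, the
# nearest preceding scale-h local maximum of `s` within the lookback
# window, else the window edge. The window never reaches past the previous
# candidate peak, so a secondary dip on an event's recovery limb cannot
# claim the pre-event baseline and be measured across the whole event.
# Matches baseline_search() peak by peak.
baseline_search_all <- function(s, peaks, lookback_samples, scale_samples) {
  lmax <- which(s == window_max(s, scale_samples))
  pos <- findInterval(peaks - 1L, lmax)
  base <- ifelse(pos >= 1L, lmax[pmax(pos, 1L)], NA_integer_)
  edge <- pmax(1L, peaks - lookback_samples)
  if (length(peaks) > 1L)
    edge[-1L] <- pmax(edge[-1L], peaks[-length(peaks)] + 1L)
  out <- ifelse(!is.na(base) & base >= edge, base, edge)
  as.integer(out)
}

#' Final search: accept candidates by amplitude
#'
#' Computes each candidate's amplitude as the peak-to-baseline difference on
#' the smoothed trace and retains events whose amplitude reaches
#' `min_amplitude_pa` (ties retained under the default `"gte"` rule) with the
#' correct polarity ordering (peak below baseline for negative-going events).
#' The baseline value is capped at the trend (the running holding-current
#' estimate) when `trend` is supplied: a noise excursion above the holding
#' level at the baseline position cannot inflate the amplitude, while an
#' event riding on the decaying tail of a previous event (baseline below the
#' trend) keeps its smaller incremental amplitude.
#'
#' @param smoothed Smoothed trace (pA).
#' @param peak_indices,baseline_indices Zero-based candidate and baseline
#'   sample indices (equal length).
#' @param min_amplitude_pa Acceptance criterion in pA.
#' @param polarity `"negative"` or `"positive"`.
#' @param amplitude_rule `"gte"` (default) or `"gt"` for the boundary.
#' @param trend Optional trend estimate (same length as `smoothed`) used to
#'   cap the baseline value.
#' @return Data frame of retained events with zero-based `peak_index`,
#'   `baseline_index`, values and `amplitude_pa`.
#' @export
finalize_events <- function(smoothed, peak_indices, baseline_indices,
                            min_amplitude_pa, polarity = "negative",
                            amplitude_rule = "gte", trend = NULL) {
  pk <- as.integer(peak_indices) + 1L
  bs <- as.integer(baseline_indices) + 1L
  pv <- smoothed[pk]
  bv <- smoothed[bs]
  if (!is.null(trend)) {
    bv <- if (polarity == "negative") pmin(bv, trend[bs]) else pmax(bv, trend[bs])
  }
  amp <- abs(pv - bv)
  sign_ok <- if (polarity == "negative") pv < bv else pv > bv
  amp_ok <- if (amplitude_rule == "gt") amp > min_amplitude_pa else amp >= min_amplitude_pa
  keep <- which(sign_ok & amp_ok)
  data.frame(peak_index = pk[keep] - 1L,
             peak_value_pa = pv[keep],
             baseline_index = bs[keep] - 1L,
             baseline_value_pa = bv[keep],
             amplitude_pa = amp[keep])
}

# Full pipeline on one sweep. Returns candidates *before* the amplitude
# criterion (amplitude column included) so that sweeps over the minimum
# amplitude can reuse one detection pass; finalize by threshold afterwards.
detect_sweep_candidates <- function(raw, params, sampling_rate_hz,
                                    trend = NULL) {
  flip <- params$polarity == "positive"
  x <- if (flip) -raw else raw
  if (is.null(trend)) {
    trend <- estimate_trend(x, sampling_rate_hz, params$trend_window_s)
  } else if (flip) {
    trend <- -trend
  }
  sm <- sg_smooth(x, params$poly_order, params$side_points)
  idx0 <- initial_search(sm, trend, "negative", params$initial_threshold_pa,
                         sampling_rate_hz, params$min_separation_ms)
  idx0 <- idx0[idx0 >= 1L]  # need room for a baseline
  if (!length(idx0)) {
    return(data.frame(peak_index = integer(0), peak_value_pa = numeric(0),
                      baseline_index = integer(0), baseline_value_pa = numeric(0),
                      amplitude_pa = numeric(0)))
  }
  L <- max(1L, round(params$baseline_max_lookback_ms / 1000 * sampling_rate_hz))
  h <- max(1L, round(params$min_separation_ms / 1000 * sampling_rate_hz))
  bidx <- baseline_search_all(sm, idx0 + 1L, L, h) - 1L
  cap <- if (identical(params$baseline_cap, "none")) NULL else trend
  cand <- finalize_events(sm, idx0, bidx, 0, "negative", "gt", trend = cap)
  if (flip) {
    cand$peak_value_pa <- -cand$peak_value_pa
    cand$baseline_value_pa <- -cand$baseline_value_pa
  }
  cand
}

apply_min_amplitude <- function(cand, min_amplitude_pa, amplitude_rule = "gte") {
  keep <- if (amplitude_rule == "gt") cand$amplitude_pa > min_amplitude_pa
          else cand$amplitude_pa >= min_amplitude_pa
  cand[keep, , drop = FALSE]
}

empty_events_df <- function() {
  data.frame(sweep_index = integer(0), peak_index = integer(0),
             peak_time_s = numeric(0), peak_value_pa = numeric(0),
             baseline_index = integer(0), baseline_value_pa = numeric(0),
             amplitude_pa = numeric(0), selected = integer(0),
             decay_tau_ms = numeric(0), decay_ok = logical(0))
}

#' Detect PSC events in a recording
#'
#' Runs the four-step pipeline on every sweep: Savitzky-Golay smoothing,
#' initial search of the smoothed trace against the running-median trend of
#' the raw trace, backward baseline search, and amplitude-based final
#' acceptance. Deterministic for fixed input and parameters.
#'
#' @param recording A [psc_recording()].
#' @param params A [detection_params()].
#' @param fit_decays If `TRUE`, fit a single-exponential decay to each event
#'   (see [fit_decay()]) and store `decay_tau_ms`/`decay_ok`.
#' @return A `psc_events` object: an event table ordered by absolute peak
#'   time with zero-based `sweep_index`/`peak_index`/`baseline_index`,
#'   values and amplitudes measured on the smoothed trace, and a `selected`
#'   flag column (all 0 after detection).
#' @export
detect <- function(recording, params = detection_params(), fit_decays = FALSE) {
  stopifnot(inherits(recording, "psc_recording"),
            inherits(params, "detection_params"))
  rate <- recording$sampling_rate_hz
  per_sweep <- lapply(seq_along(recording$sweeps) - 1L, function(si) {
    cand <- detect_sweep_candidates(recording$sweeps[[si + 1L]], params, rate)
    ev <- apply_min_amplitude(cand, params$min_amplitude_pa, params$amplitude_rule)
    if (!nrow(ev)) return(NULL)
    ev$sweep_index <- si
    ev$peak_time_s <- sample_time(recording, si, ev$peak_index)
    ev
  })
  events <- do.call(rbind, per_sweep)
  if (is.null(events)) {
    events <- empty_events_df()
  } else {
    events$selected <- 0L
    events$decay_tau_ms <- NA_real_
    events$decay_ok <- NA
    events <- events[order(events$peak_time_s), names(empty_events_df())]
    rownames(events) <- NULL
  }
  out <- structure(list(events = events, params = params,
                        overrides = list(),
                        sampling_rate_hz = rate,
                        sweep_duration_s = recording$sweep_duration_s,
                        n_sweeps = n_sweeps(recording)),
                   class = "psc_events")
  if (fit_decays) out <- fit_all_decays(out, recording)
  out
}

#' @export
print.psc_events <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<psc_events> %d event(s) over %d sweep(s); %d selected\n",
              nrow(ev), x$n_sweeps, sum(ev$selected)))
  if (nrow(ev))
    cat(sprintf("  mean amplitude %.2f pA; params: poly %d, side %d, min amp %g\n",
                mean(ev$amplitude_pa), x$params$poly_order,
                x$params$side_points, x$params$min_amplitude_pa))
  invisible(x)
}

#' Re-run detection on a single sweep
#'
#' Replaces the events of one sweep with a fresh detection using override
#' parameters; events in every other sweep are untouched. The override is
#' recorded in the per-sweep log so a result remains replayable. Selection
#' flags are reset (the selected block may no longer be contiguous
#' otherwise).
#'
#' @param recording The [psc_recording()] the events came from.
#' @param eventset A `psc_events` object from [detect()].
#' @param sweep_index Zero-based sweep to redo.
#' @param params_override A [detection_params()] for that sweep.
#' @return The updated `psc_events`.
#' @export
redetect_sweep <- function(recording, eventset, sweep_index, params_override) {
  stopifnot(inherits(eventset, "psc_events"),
            inherits(params_override, "detection_params"))
  si <- as.integer(sweep_index)
  if (si < 0L || si >= n_sweeps(recording))
    stop_format(sprintf("sweep_index %d out of range [0, %d]", si,
                        n_sweeps(recording) - 1L))
  rate <- recording$sampling_rate_hz
  cand <- detect_sweep_candidates(recording$sweeps[[si + 1L]], params_override, rate)
  ev <- apply_min_amplitude(cand, params_override$min_amplitude_pa,
                            params_override$amplitude_rule)
  keep <- eventset$events[eventset$events$sweep_index != si, , drop = FALSE]
  if (nrow(ev)) {
    ev$sweep_index <- si
    ev$peak_time_s <- sample_time(recording, si, ev$peak_index)
    ev$selected <- 0L
    ev$decay_tau_ms <- NA_real_
    ev$decay_ok <- NA
    ev <- ev[, names(empty_events_df())]
    keep <- rbind(keep, ev)
  }
  keep$selected <- 0L
  keep <- keep[order(keep$peak_time_s), , drop = FALSE]
  rownames(keep) <- NULL
  eventset$events <- keep
  eventset$overrides[[as.character(si)]] <- params_override
  eventset
}

#' Delete one event
#'
#' Removes a (false-positive) event by its zero-based position in the event
#' table; a deleted true event can be restored with [redetect_sweep()].
#'
#' @param eventset A `psc_events` object.
#' @param event_index Zero-based row index into the event table.
#' @return The updated `psc_events`.
#' @export
delete_event <- function(eventset, event_index) {
  stopifnot(inherits(eventset, "psc_events"))
  i <- as.integer(event_index) + 1L
  if (is.na(i) || i < 1L || i > nrow(eventset$events))
    stop_format(sprintf("no event with index %s", as.character(event_index)))
  eventset$events <- eventset$events[-i, , drop = FALSE]
  rownames(eventset$events) <- NULL
  eventset
}

#' Select a contiguous block of events
#'
#' Flags exactly `n` consecutive events (in global time order) starting at
#' zero-based `start_event_index` with `selected = 1`; all other events are
#' set to 0. Re-selection overwrites any previous flags.
#'
#' @param eventset A `psc_events` object.
#' @param start_event_index Zero-based index of the first event to select.
#' @param n Number of events to select.
#' @return The updated `psc_events`.
#' @export
select_events <- function(eventset, start_event_index, n) {
  stopifnot(inherits(eventset, "psc_events"))
  total <- nrow(eventset$events)
  s <- as.integer(start_event_index)
  n <- as.integer(n)
  if (s < 0L || n < 0L) stop_format("start index and count must be non-negative")
  if (s + n > total)
    stop_format(sprintf(
      "cannot select %d events from index %d: only %d remain (%d short)",
      n, s, total - s, s + n - total))
  sel <- integer(total)
  if (n > 0L) sel[(s + 1L):(s + n)] <- 1L
  eventset$events$selected <- sel
  eventset
}

#' Per-sweep summary table
#'
#' @param recording The [psc_recording()] analysed.
#' @param eventset The `psc_events` from [detect()].
#' @return Data frame with one row per sweep: zero-based `sweep_index`,
#'   `mean_holding_current_pa` (mean of the raw samples), `n_events`, and
#'   `mean_amplitude_pa` (`NA` for sweeps without events).
#' @export
sweep_summaries <- function(recording, eventset) {
  stopifnot(inherits(recording, "psc_recording"), inherits(eventset, "psc_events"))
  ev <- eventset$events
  do.call(rbind, lapply(seq_along(recording$sweeps) - 1L, function(si) {
    amps <- ev$amplitude_pa[ev$sweep_index == si]
    data.frame(sweep_index = si,
               mean_holding_current_pa = mean(recording$sweeps[[si + 1L]]),
               n_events = length(amps),
               mean_amplitude_pa = if (length(amps)) mean(amps) else NA_real_)
  }))
}

#' Totals over an event set
#'
#' Event counts, mean amplitude and mean inter-event interval (IEI,
#' differences of consecutive absolute peak times) for all events and for
#' the selected subset.
#'
#' @param eventset A `psc_events` object.
#' @return Data frame with rows `"total"` and `"selected"` and columns `n`,
#'   `mean_amplitude_pa`, `mean_iei_s` (`NA` when fewer than 2 events).
#' @export
summarize_events <- function(eventset) {
  stopifnot(inherits(eventset, "psc_events"))
  block <- function(ev) {
    data.frame(n = nrow(ev),
               mean_amplitude_pa = if (nrow(ev)) mean(ev$amplitude_pa) else NA_real_,
               mean_iei_s = if (nrow(ev) >= 2) mean(diff(ev$peak_time_s)) else NA_real_)
  }
  ev <- eventset$events
  out <- rbind(block(ev), block(ev[ev$selected == 1L, , drop = FALSE]))
  out <- cbind(scope = c("total", "selected"), out)
  rownames(out) <- NULL
  out
}

#' Convert detection results to a unit record
#'
#' @param eventset A `psc_events` object.
#' @param name Unit name (file base name without extension).
#' @return A [unit_record()] with absolute peak times, amplitudes and
#'   selection flags.
#' @export
as_unit_record <- function(eventset, name) {
  stopifnot(inherits(eventset, "psc_events"))
  ev <- eventset$events
  unit_record(name, data.frame(time_s = ev$peak_time_s,
                               amplitude_pa = ev$amplitude_pa,
                               selected = ev$selected))
}
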