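#' Fit a single-exponential decay to one event
#'
#' Least-squares fit of `y(t) = y_inf + (y_peak - y_inf) * exp(-(t - t_peak)/tau)`
#' to the samples after the event peak. The fit window runs from the peak to
#' the next event's onset (its baseline sample) or 50 ms past the peak,
#' whichever comes first. A fit is flagged as failed (never silently zero)
#' when it does not converge or when tau falls outside (0, 1000] ms.
#'
#' @param trace Raw or smoothed sample vector (pA) of the event's sweep.
#' @param peak_index Zero-based peak sample index.
#' @param sampling_rate_hz Sampling rate (samples/s).
#' @param end_index Optional zero-based exclusive end of the fit window
#'   (e.g. the next event's baseline index); capped at peak + 50 ms.
#' @return List with `tau_ms`, `ok` (logical), `y_inf`, `y_peak`, `n_points`.
#' @export
fit_decay <- function(trace, peak_index, sampling_rate_hz, end_index = NULL) {
  p <- as.integer(peak_index) + 1L
  n <- length(trace)
  cap <- p + round(0.05 * sampling_rate_hz)
  hi <- min(n, cap)
  if (!is.null(end_index)) hi <- min(hi, as.integer(end_index))
  failed <- list(tau_ms = NA_real_, ok = FALSE, y_inf = NA_real_,
                 y_peak = trace[p], n_points = max(0L, hi - p + 1L))
  if (hi - p + 1L < 10L) return(failed)
  t_ms <- ((p:hi) - p) / sampling_rate_hz * 1000
  y <- trace[p:hi]
  if (stats::sd(y) < .Machine$double.eps^0.5) return(failed)
  # starting values: asymptote from the window tail, tau from a log-linear
  # fit of the deviation; Levenberg-Marquardt refinement is robust where
  # plain Gauss-Newton stalls (e.g. the zero-residual noiseless case)
  yinf0 <- mean(y[max(1L, round(0.9 * length(y))):length(y)])
  amp0 <- y[1L] - yinf0
  if (abs(amp0) < .Machine$double.eps^0.5) return(failed)
  dev <- (y - yinf0) / amp0
  use <- which(dev > 0.05)
  tau0 <- if (length(use) >= 3L) {
    sl <- stats::coef(stats::lm(log(dev[use]) ~ t_ms[use]))[2L]
    if (is.finite(sl) && sl < 0) -1 / sl else 5
  } else 5
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ yinf + amp * exp(-t_ms / tau),
                      start = list(yinf = yinf0, amp = amp0,
                                   tau = min(max(tau0, 0.1), 500))),
    error = function(e) NULL)
  if (is.null(fit)) return(failed)
  cf <- stats::coef(fit)
  tau <- cf[["tau"]]
  if (!is.finite(tau) || tau <= 0 || tau > 1000) return(failed)
  list(tau_ms = unname(tau), ok = TRUE, y_inf = unname(cf[["yinf"]]),
       y_peak = unname(cf[["yinf"]] + cf[["amp"]]), n_points = length(y))
}

# fit decays for every event in an event set, windowed at the next event's
# baseline within the same sweep
fit_all_decays <- function(eventset, recording) {
  ev <- eventset$events
  if (!nrow(ev)) return(eventset)
  rate <- recording$sampling_rate_hz
  for (si in unique(ev$sweep_index)) {
    rows <- which(ev$sweep_index == si)
    rows <- rows[order(ev$peak_index[rows])]
    trace <- recording$sweeps[[si + 1L]]
    for (k in seq_along(rows)) {
      i <- rows[k]
      end <- if (k < length(rows)) ev$baseline_index[rows[k + 1L]] else NULL
      f <- fit_decay(trace, ev$peak_index[i], rate, end)
      ev$decay_tau_ms[i] <- f$tau_ms
      ev$decay_ok[i] <- f$ok
    }
  }
  eventset$events <- ev
  eventset
}
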