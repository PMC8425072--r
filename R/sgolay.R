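# Savitzky-Golay smoothing: least-squares polynomial fit over a moving
# window, evaluated at the window centre. Interior points use a precomputed
# convolution kernel (the centre row of the hat matrix); near the edges the
# window shrinks asymmetrically to the available samples so no margin is
# lost and events near sweep boundaries stay detectable.

sg_center_kernel <- function(poly_order, side_points) {
  m <- side_points
  X <- outer(-m:m, 0:poly_order, `^`)
  # value of the LS fit at the centre = e_{m+1}' X (X'X)^{-1} X' y
  H <- X %*% solve(crossprod(X), t(X))
  H[m + 1L, ]
}

sg_edge_value <- function(x, i, poly_order, side_points) {
  # fit over the samples available around i, evaluate at i
  lo <- max(1L, i - side_points)
  hi <- min(length(x), i + side_points)
  pos <- (lo:hi) - i
  p <- min(poly_order, length(pos) - 1L)
  X <- outer(pos, 0:p, `^`)
  beta <- qr.solve(X, x[lo:hi])
  beta[1L]
}

#' Savitzky-Golay smoothing of a trace
#'
#' Local polynomial regression of degree `poly_order` over a centred window
#' of `2 * side_points + 1` samples, evaluated at the centre. Within
#' `side_points` samples of either end the window shrinks to the available
#' samples (degree reduced if needed) instead of padding.
#'
#' @param trace Numeric sample vector (pA).
#' @param poly_order Polynomial degree (>= 1).
#' @param side_points Half-window size; the full window must be shorter than
#'   the trace.
#' @return Smoothed vector of the same length.
#' @export
sg_smooth <- function(trace, poly_order, side_points) {
  n <- length(trace)
  m <- as.integer(side_points)
  p <- as.integer(poly_order)
  if (p < 1L || 2L * m + 1L <= p)
    stop_format("need 2 * side_points + 1 > poly_order >= 1")
  if (2L * m + 1L >= n)
    stop_format(sprintf("smoothing window (%d) must be shorter than the trace (%d)",
                        2L * m + 1L, n))
  kern <- sg_center_kernel(p, m)
  out <- as.numeric(stats::filter(trace, kern, sides = 2))
  for (i in seq_len(m)) {
    out[i] <- sg_edge_value(trace, i, p, m)
    out[n - i + 1L] <- sg_edge_value(trace, n - i + 1L, p, m)
  }
  out
}

#' Trend (slowly varying baseline) of a trace
#'
#' Centred running median over a `trend_window_s`-wide window, edge-padded by
#' reflection. The median is insensitive to PSC-scale transients, so the
#' trend tracks the holding current and slow drift while single events barely
#' perturb it.
#'
#' @param trace Numeric sample vector (pA).
#' @param sampling_rate_hz Sampling rate (samples/s).
#' @param trend_window_s Window width in seconds (default 0.5).
#' @return Trend vector of the same length.
#' @export
estimate_trend <- function(trace, sampling_rate_hz, trend_window_s = 0.5) {
  n <- length(trace)
  k <- round(trend_window_s * sampling_rate_hz)
  if (k %% 2 == 0) k <- k + 1
  if (k > n) k <- if (n %% 2 == 1) n else n - 1L
  if (k < 3) return(trace)
  m <- (k - 1L) %/% 2L
  padded <- c(trace[(m + 1L):2L], trace, trace[(n - 1L):(n - m)])
  sm <- stats::runmed(padded, k, endrule = "keep")
  sm[(m + 1L):(m + n)]
}
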