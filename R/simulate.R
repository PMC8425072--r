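# Synthetic PSC benchmark: biexponential quantal-conductance events with
# jittered kinetics, placed uniformly in a long zero-baseline sweep, with
# white Gaussian noise added on top. The generator's defaults are the
# benchmark's study conditions: 250 events in 250 s at 10 kHz, tau jitter
# N(1, 0.3), mean true peak amplitude calibrated to 27.85 pA.

with_rng_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", globalenv()) else NULL
    on.exit(
      if (had) assign(".Random.seed", old, globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(code)
}

#' Biexponential kernel parameters
#'
#' @param A_nS Peak-amplitude coefficient in nS (negative for inward
#'   currents). Default -12.783.
#' @param tau1_ms Rise time constant (ms). Default 0.5.
#' @param tau2_ms Decay time constant (ms), must exceed `tau1_ms`. Default 3.
#' @return A `kernel_params` object.
#' @export
kernel_params <- function(A_nS = -12.783, tau1_ms = 0.5, tau2_ms = 3.0) {
  check_scalar_number(A_nS, "A_nS")
  check_scalar_number(tau1_ms, "tau1_ms", positive = TRUE)
  check_scalar_number(tau2_ms, "tau2_ms", positive = TRUE)
  if (A_nS == 0) stop_format("'A_nS' must be nonzero")
  if (tau2_ms <= tau1_ms) stop_format("'tau2_ms' must exceed 'tau1_ms'")
  structure(list(A_nS = A_nS, tau1_ms = tau1_ms, tau2_ms = tau2_ms),
            class = "kernel_params")
}

# normalisation factor A' = tau2^(tau1/(tau1 - tau2)) / tau1, evaluated at
# the nominal (unscaled) time constants
kernel_norm <- function(tau1, tau2) tau2^(tau1 / (tau1 - tau2)) / tau1

# time of the kernel extremum for given (possibly scaled) time constants
kernel_peak_time_ms <- function(tau1, tau2) {
  tau1 * tau2 / (tau2 - tau1) * log(tau2 / tau1)
}

#' Evaluate the quantal-conductance kernel
#'
#' Causal biexponential waveform
#' `g(t) = (A / A') * (-exp(-t / tau1) + exp(-t / tau2))` for `t > 0` and 0
#' for `t <= 0`, with normalisation `A' = tau2^(tau1/(tau1 - tau2)) / tau1`
#' evaluated at the kernel's nominal time constants. Optional scaled time
#' constants (per-event kinetic jitter) change the bracket but not `A'`, so
#' jittered events genuinely vary in peak amplitude; set
#' `renormalize = TRUE` to recompute `A'` per call instead.
#'
#' @param params A [kernel_params()].
#' @param t_ms Time points in ms (0 is the event onset).
#' @param tau1_ms,tau2_ms Optional scaled time constants; default nominal.
#' @param renormalize Recompute the normalisation at the scaled constants.
#' @return Conductance values (same units as `A_nS`).
#' @export
psc_kernel <- function(params, t_ms, tau1_ms = params$tau1_ms,
                       tau2_ms = params$tau2_ms, renormalize = FALSE) {
  if (tau2_ms <= tau1_ms || tau1_ms <= 0)
    stop_format("need tau2 > tau1 > 0")
  Ap <- if (renormalize) kernel_norm(tau1_ms, tau2_ms)
        else kernel_norm(params$tau1_ms, params$tau2_ms)
  out <- numeric(length(t_ms))
  pos <- t_ms > 0
  tp <- t_ms[pos]
  out[pos] <- params$A_nS / Ap * (-exp(-tp / tau1_ms) + exp(-tp / tau2_ms))
  out
}

#' Benchmark simulation settings
#'
#' @param n_events Number of simulated events (default 250).
#' @param duration_s Length of the single-sweep waveform in s (default 250).
#' @param sampling_rate_hz Sampling rate (default 10000).
#' @param tau_scale_mean,tau_scale_sd Mean and SD of the normal kinetic
#'   jitter factor(s) (defaults 1 and 0.3); draws are resampled while a draw
#'   is <= 0.1 or the scaled constants would violate tau2 > tau1.
#' @param tau_jitter `"shared"` (default): one draw per event multiplies
#'   both time constants, so the kinetics vary while the analytic peak
#'   amplitude stays at the calibrated value; `"independent"`: separate
#'   draws for tau1 and tau2, which also disperses the peak amplitudes.
#' @param seed RNG seed for event placement and jitter.
#' @param amp_calibration_mean_pa Target mean of the true peak amplitudes in
#'   pA (default 27.85); one global scale factor maps conductance to current.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_events = 250L, duration_s = 250, sampling_rate_hz = 10000,
                       tau_scale_mean = 1.0, tau_scale_sd = 0.3,
                       tau_jitter = c("shared", "independent"), seed = NULL,
                       amp_calibration_mean_pa = 27.85) {
  tau_jitter <- match.arg(tau_jitter)
  check_scalar_number(n_events, "n_events", integer = TRUE)
  if (n_events < 0) stop_format("'n_events' must be >= 0")
  check_scalar_number(duration_s, "duration_s", positive = TRUE)
  check_scalar_number(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  check_scalar_number(tau_scale_sd, "tau_scale_sd")
  check_scalar_number(amp_calibration_mean_pa, "amp_calibration_mean_pa",
                      positive = TRUE)
  structure(list(n_events = as.integer(n_events), duration_s = duration_s,
                 sampling_rate_hz = sampling_rate_hz,
                 tau_scale_mean = tau_scale_mean, tau_scale_sd = tau_scale_sd,
                 tau_jitter = tau_jitter, seed = seed,
                 amp_calibration_mean_pa = amp_calibration_mean_pa),
            class = "sim_config")
}

#' Simulate a clean PSC benchmark recording
#'
#' Places `n_events` biexponential events at uniformly random onsets in
#' `(0, duration - 0.05)` s of a zero-baseline single-sweep trace. Each
#' event's tau1 and tau2 are multiplied by normal jitter draws (one shared
#' draw per event by default, see [sim_config()]). All event amplitudes are
#' rescaled by one global constant so that the mean true (analytic) peak
#' amplitude equals `amp_calibration_mean_pa`; the trace is negative-going
#' (inward currents).
#'
#' @param config A [sim_config()].
#' @param kernel A [kernel_params()].
#' @return List with `recording` (a clean, noise-free [psc_recording()]) and
#'   `truth`: a data frame with one row per event (`onset_time_s`,
#'   `peak_time_s`, `true_peak_amplitude_pa`, `tau1_ms`, `tau2_ms`), ordered
#'   by onset.
#' @export
simulate_recording <- function(config = sim_config(), kernel = kernel_params()) {
  stopifnot(inherits(config, "sim_config"), inherits(kernel, "kernel_params"))
  rate <- config$sampling_rate_hz
  n_samp <- round(config$duration_s * rate)
  n <- config$n_events
  if (n == 0L) {
    rec <- psc_recording(list(numeric(n_samp)), rate, config$duration_s,
                         source_path = "<simulated>")
    truth <- data.frame(onset_time_s = numeric(0), peak_time_s = numeric(0),
                        true_peak_amplitude_pa = numeric(0),
                        tau1_ms = numeric(0), tau2_ms = numeric(0))
    return(list(recording = rec, truth = truth))
  }
  sim <- with_rng_seed(config$seed, {
    onsets <- sort(stats::runif(n, 0, config$duration_s - 0.05))
    draw <- function() {
      repeat {
        j <- stats::rnorm(1, config$tau_scale_mean, config$tau_scale_sd)
        if (j > 0.1) return(j)
      }
    }
    t1 <- numeric(n); t2 <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        if (config$tau_jitter == "shared") {
          k <- draw()
          a <- kernel$tau1_ms * k
          b <- kernel$tau2_ms * k
        } else {
          a <- kernel$tau1_ms * draw()
          b <- kernel$tau2_ms * draw()
        }
        if (b > a) { t1[i] <- a; t2[i] <- b; break }
      }
    }
    list(onsets = onsets, t1 = t1, t2 = t2)
  })
  Ap <- kernel_norm(kernel$tau1_ms, kernel$tau2_ms)
  tpk <- kernel_peak_time_ms(sim$t1, sim$t2)
  peak_g <- kernel$A_nS / Ap *
    (-exp(-tpk / sim$t1) + exp(-tpk / sim$t2))   # nS, negative
  cal <- config$amp_calibration_mean_pa / mean(abs(peak_g))
  trace <- numeric(n_samp)
  for (i in seq_len(n)) {
    i0 <- floor(sim$onsets[i] * rate) + 1L       # first sample with t > 0
    span_ms <- tpk[i] + 12 * sim$t2[i]           # amplitude < 1e-5 of peak beyond
    i1 <- min(n_samp, i0 + ceiling(span_ms / 1000 * rate))
    if (i0 > n_samp) next
    t_ms <- ((i0:i1) - 1L) / rate * 1000 - sim$onsets[i] * 1000
    trace[i0:i1] <- trace[i0:i1] +
      cal * psc_kernel(kernel, t_ms, sim$t1[i], sim$t2[i])
  }
  truth <- data.frame(onset_time_s = sim$onsets,
                      peak_time_s = sim$onsets + tpk / 1000,
                      true_peak_amplitude_pa = cal * abs(peak_g),
                      tau1_ms = sim$t1, tau2_ms = sim$t2)
  rec <- psc_recording(list(trace), rate, config$duration_s,
                       source_path = "<simulated>")
  list(recording = rec, truth = truth)
}

#' Add white Gaussian noise to a recording
#'
#' @param recording A [psc_recording()].
#' @param sigma_pa Noise standard deviation in pA (>= 0; 0 is the identity).
#' @param seed Optional RNG seed for reproducibility.
#' @return The noisy [psc_recording()].
#' @export
add_noise <- function(recording, sigma_pa, seed = NULL) {
  stopifnot(inherits(recording, "psc_recording"))
  check_scalar_number(sigma_pa, "sigma_pa")
  if (sigma_pa < 0) stop_format("'sigma_pa' must be >= 0")
  if (sigma_pa == 0) return(recording)
  with_rng_seed(seed, {
    recording$sweeps <- lapply(recording$sweeps, function(s)
      s + stats::rnorm(length(s), 0, sigma_pa))
  })
  recording
}

#' Write / read the simulation ground-truth table
#'
#' Tab-delimited with a header line (`onset_time_s`, `peak_time_s`,
#' `true_peak_amplitude_pa`, `tau1_ms`, `tau2_ms`).
#'
#' @param truth Truth data frame from [simulate_recording()].
#' @param path File path.
#' @return `write_sim_truth`: `invisible(path)`; `read_sim_truth`: the
#'   truth data frame.
#' @export
write_sim_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  utils::read.table(path, sep = "\t", header = TRUE)
}
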