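# Fixtures are generated in code at test time; nothing is stored on disk.

# A one-sweep recording holding a single biexponential event with a known
# analytic peak time and amplitude (zero baseline, optional noise).
single_event_recording <- function(amplitude_pa = 30, onset_s = 0.5,
                                   duration_s = 1, rate = 10000,
                                   tau1_ms = 0.5, tau2_ms = 3,
                                   sigma_pa = 0, seed = NULL) {
  kp <- kernel_params()
  n <- round(duration_s * rate)
  t_ms <- ((seq_len(n) - 1) / rate - onset_s) * 1000
  g <- psc_kernel(kp, t_ms, tau1_ms, tau2_ms)
  peak_rel_ms <- tau1_ms * tau2_ms / (tau2_ms - tau1_ms) * log(tau2_ms / tau1_ms)
  scale <- amplitude_pa / max(abs(g))
  rec <- psc_recording(list(scale * g), rate, duration_s)
  if (sigma_pa > 0) rec <- add_noise(rec, sigma_pa, seed = seed)
  list(recording = rec,
       peak_time_s = onset_s + peak_rel_ms / 1000,
       amplitude_pa = amplitude_pa)
}

# Small multi-event benchmark shared by detection/editing tests: 20 events
# in 20 s, one sweep, moderate noise. Cached per test run.
mini_bench_env <- new.env(parent = emptyenv())
mini_bench <- function(sigma = 2) {
  key <- paste0("s", sigma)
  if (is.null(mini_bench_env[[key]])) {
    sim <- simulate_recording(sim_config(n_events = 20, duration_s = 20,
                                         seed = 7001))
    mini_bench_env[[key]] <- list(
      sim = sim,
      noisy = add_noise(sim$recording, sigma, seed = 7002))
  }
  mini_bench_env[[key]]
}

# The standard 250-event / 250-s benchmark, cached across acceptance tests.
std_bench_env <- new.env(parent = emptyenv())
std_bench <- function(sigma = 0, seed = 4242) {
  if (is.null(std_bench_env$sim))
    std_bench_env$sim <- simulate_recording(sim_config(seed = seed))
  key <- paste0("s", sigma)
  if (is.null(std_bench_env[[key]]))
    std_bench_env[[key]] <- add_noise(std_bench_env$sim$recording, sigma,
                                      seed = seed + round(100 * sigma))
  list(truth = std_bench_env$sim$truth, noisy = std_bench_env[[key]])
}

# Brute-force maximum-cardinality matching (min total |dt| among maximum
# matchings) for small problems; oracle for the greedy matcher.
brute_force_match <- function(det, tru, tol) {
  best <- list(n = -1, cost = Inf)
  recurse <- function(i, used, n, cost) {
    if (i > length(det)) {
      if (n > best$n || (n == best$n && cost < best$cost))
        best <<- list(n = n, cost = cost)
      return(invisible())
    }
    recurse(i + 1L, used, n, cost)            # leave det i unmatched
    for (j in seq_along(tru)) {
      dt <- abs(det[i] - tru[j])
      if (!used[j] && dt <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, n + 1L, cost + dt)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(tru)), 0L, 0)
  best
}

expect_events_equal <- function(a, b) {
  expect_equal(a$events$peak_index, b$events$peak_index)
  expect_equal(a$events$amplitude_pa, b$events$amplitude_pa)
  expect_equal(a$events$baseline_index, b$events$baseline_index)
}
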