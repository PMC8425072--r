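test_that("redetect replaces one sweep and leaves the others bit-identical", {
  sim <- simulate_recording(sim_config(n_events = 12, duration_s = 12, seed = 501))
  # reshape into 3 sweeps of 4 s
  tr <- sim$recording$sweeps[[1]]
  rec <- psc_recording(split(tr, rep(0:2, each = length(tr) / 3)), 10000, 4)
  noisy <- add_noise(rec, 2, seed = 502)
  ev <- detect(noisy, detection_params())

  # identical override is idempotent
  same <- redetect_sweep(noisy, ev, 1, detection_params())
  expect_events_equal(same, ev)

  # a different criterion changes only sweep 1
  low <- redetect_sweep(noisy, ev, 1, detection_params(min_amplitude_pa = 5))
  other <- function(e) e$events[e$events$sweep_index != 1, ]
  expect_identical(other(low)[, names(other(low)) != "selected"],
                   other(ev)[, names(other(ev)) != "selected"])
  expect_gte(sum(low$events$sweep_index == 1), sum(ev$events$sweep_index == 1))
  expect_identical(names(low$overrides), "1")

  expect_error(redetect_sweep(noisy, ev, 5, detection_params()),
               "out of range", class = "psc_format_error")
})

test_that("a borderline event missed under one setting is found by redetect", {
  # a narrow event (tau2 = 1 ms) attenuates fast with smoothing: invisible
  # at side 27, recovered at side 10 while the broad event persists
  rate <- 10000
  n <- 10000
  t_ms <- (seq_len(n) - 1) / rate * 1000
  kp <- kernel_params()
  broad <- psc_kernel(kp, t_ms - 200)
  broad <- broad / max(abs(broad)) * 30
  narrow <- psc_kernel(kp, t_ms - 600, tau1_ms = 0.3, tau2_ms = 1)
  narrow <- narrow / max(abs(narrow)) * 16
  rec <- psc_recording(list(broad + narrow), rate, 1)

  ev27 <- detect(rec, detection_params(side_points = 27))
  expect_equal(nrow(ev27$events), 1L)
  ev10 <- redetect_sweep(rec, ev27, 0, detection_params(side_points = 10))
  expect_equal(nrow(ev10$events), 2L)
  expect_true(any(abs(ev10$events$peak_time_s - 0.6) < 0.002))
})

test_that("delete removes exactly one event and redetect restores it", {
  mb <- mini_bench()
  ev <- detect(mb$noisy, detection_params())
  n0 <- nrow(ev$events)
  gone <- delete_event(ev, 3)
  expect_equal(nrow(gone$events), n0 - 1L)
  expect_false(ev$events$peak_time_s[4] %in% gone$events$peak_time_s)

  restored <- redetect_sweep(mb$noisy, gone,
                             ev$events$sweep_index[4], detection_params())
  expect_true(ev$events$peak_time_s[4] %in% restored$events$peak_time_s)

  expect_error(delete_event(ev, n0), "no event", class = "psc_format_error")
})

test_that("selection flags a contiguous block and summaries recompute over it", {
  sim <- simulate_recording(sim_config(n_events = 60, duration_s = 60, seed = 503))
  ev <- detect(add_noise(sim$recording, 2, seed = 504))
  n <- nrow(ev$events)
  expect_gte(n, 50)

  all_sel <- select_events(ev, 0, n)
  expect_true(all(all_sel$events$selected == 1L))
  s <- summarize_events(all_sel)
  expect_equal(s$mean_amplitude_pa[1], s$mean_amplitude_pa[2])
  expect_equal(s$mean_iei_s[1], s$mean_iei_s[2])

  part <- select_events(ev, 10, 30)
  expect_equal(sum(part$events$selected), 30L)
  expect_equal(which(part$events$selected == 1L), 11:40)
  # re-selection overwrites
  again <- select_events(part, 0, 5)
  expect_equal(which(again$events$selected == 1L), 1:5)
  # recompute oracle for the selected block
  sp <- summarize_events(part)
  expect_equal(sp$mean_amplitude_pa[2], mean(part$events$amplitude_pa[11:40]))

  expect_error(select_events(ev, n - 5, 10), "short",
               class = "psc_format_error")
})

test_that("event and sweep summaries follow their definitions", {
  flat <- psc_recording(list(rep(-45, 5000), rep(-45, 5000)), 10000, 0.5)
  ev <- detect(flat)
  ss <- sweep_summaries(flat, ev)
  expect_equal(ss$mean_holding_current_pa, c(-45, -45))
  expect_equal(ss$n_events, c(0L, 0L))
  expect_true(all(is.na(ss$mean_amplitude_pa)))

  # hand-built event set: events at t = 1, 2, 4 s -> IEIs {1, 2}
  ev$events <- data.frame(sweep_index = 0L, peak_index = c(100L, 200L, 300L),
                          peak_time_s = c(1, 2, 4),
                          peak_value_pa = -c(10, 20, 30),
                          baseline_index = c(50L, 150L, 250L),
                          baseline_value_pa = 0,
                          amplitude_pa = c(10, 20, 30),
                          selected = c(0L, 1L, 1L),
                          decay_tau_ms = NA_real_, decay_ok = NA)
  s <- summarize_events(ev)
  expect_equal(s$n, c(3L, 2L))
  expect_equal(s$mean_iei_s[1], 1.5)
  expect_equal(s$mean_amplitude_pa, c(20, 25))

  # single event: IEI missing
  ev$events <- ev$events[1, ]
  s1 <- summarize_events(ev)
  expect_equal(s1$n[1], 1L)
  expect_true(is.na(s1$mean_iei_s[1]))

  # conservation: per-sweep counts sum to the total
  mb <- mini_bench()
  evb <- detect(mb$noisy)
  expect_equal(sum(sweep_summaries(mb$noisy, evb)$n_events), nrow(evb$events))
})

test_that("decay fitting recovers known time constants and flags failures", {
  rate <- 10000
  t_ms <- (0:499) / rate * 1000
  # pure exponential, tau = 3 ms
  y <- -5 + (-30 + 5) * exp(-t_ms / 3)
  f <- fit_decay(y, 0, rate)
  expect_true(f$ok)
  expect_equal(f$tau_ms, 3, tolerance = 0.01)

  # flat post-peak segment: flagged failure, never silently zero
  expect_false(fit_decay(rep(-10, 500), 0, rate)$ok)
  expect_true(is.na(fit_decay(rep(-10, 500), 0, rate)$tau_ms))

  # too-short window: flagged failure
  expect_false(fit_decay(y[1:5], 0, rate)$ok)

  # kernel event: fitted tau within 15% of the scaled tau2
  fx <- single_event_recording(amplitude_pa = 30, tau2_ms = 4)
  ev <- detect(fx$recording, detection_params(), fit_decays = TRUE)
  expect_true(ev$events$decay_ok[1])
  expect_lt(abs(ev$events$decay_tau_ms[1] - 4) / 4, 0.15)
})
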