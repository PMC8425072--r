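make_unit_tree <- function() {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  dir.create(file.path(root, "sub"))
  dir.create(file.path(root, "EXCLUDED"))
  u <- function(name, times, amps, sel = 1L) {
    write_unit_file(unit_record(name, data.frame(time_s = times,
                                                 amplitude_pa = amps,
                                                 selected = sel)),
                    file.path(root, paste0(name, ".txt")))
  }
  u("180508_VC_#01", 1:10, seq(10, 28, 2))
  u("180531_VC_#02", seq(0.5, 5, 0.5), seq(12, 30, 2))
  write_unit_file(unit_record("180508_SC_#01",
                              data.frame(time_s = c(2, 4), amplitude_pa = c(15, 25),
                                         selected = c(1L, 1L))),
                  file.path(root, "sub", "180508_SC_#01.txt"))
  write_unit_file(unit_record("180599_VC_#99",
                              data.frame(time_s = 1, amplitude_pa = 11, selected = 1L)),
                  file.path(root, "EXCLUDED", "180599_VC_#99.txt"))
  root
}

test_that("wildcard retrieval matches base names case-insensitively with exclusions", {
  root <- make_unit_tree()
  hits <- find_unit_files(root, "1805??_VC_#??")
  expect_length(hits, 3L)  # includes the one under EXCLUDED
  expect_true(any(grepl("180508_VC_#01", hits)))

  # excluded folder names are case-insensitive, at any depth
  hits2 <- find_unit_files(root, "1805??_VC_#??", exclude_folders = "excluded")
  expect_length(hits2, 2L)
  expect_false(any(grepl("180599", hits2)))

  # literal mismatch: SC pattern does not match VC files
  expect_length(find_unit_files(root, "??????_SC_#??",
                                exclude_folders = "excluded"), 1L)
  # '?' is exactly one character, and matching ignores the extension
  expect_length(find_unit_files(root, "180508_VC_#0?"), 1L)
  expect_length(find_unit_files(root, "180508_VC_#?"), 0L)
  # case-insensitive pattern match
  expect_length(find_unit_files(root, "1805??_vc_#??",
                                exclude_folders = "excluded"), 2L)
  # deterministic order
  expect_identical(hits2, sort(hits2, method = "radix"))

  expect_error(find_unit_files(file.path(root, "nope"), "?"),
               class = "psc_format_error")
})

test_that("loading tolerates individual bad files and reports them", {
  root <- make_unit_tree()
  bad <- file.path(root, "badunit.txt")
  writeLines(c("2\t10\t0", "1\t10\t0"), bad)  # non-monotone
  paths <- c(find_unit_files(root, "1805??_VC_#??", "excluded"), bad)
  res <- load_units(paths)
  expect_length(res$records, 2L)
  expect_length(res$failures, 1L)
  expect_match(names(res$failures), "badunit")
  # order-preserving
  expect_equal(vapply(res$records, function(r) r$name, character(1)),
               c("180508_VC_#01", "180531_VC_#02"))

  expect_error(load_units(character(0)), class = "psc_format_error")
  expect_error(load_units(bad), "all unit files failed",
               class = "psc_format_error")
})

test_that("group summaries follow the frequency definition and closed forms", {
  # 10 events at 1..10 s, all selected: frequency 1 Hz in both scopes
  u <- unit_record("a", data.frame(time_s = 1:10,
                                   amplitude_pa = rep(10, 10), selected = 1L))
  gs <- summarize_group(list(u))
  expect_equal(gs$per_unit$frequency_t, 1)
  expect_equal(gs$per_unit$frequency_s, 1)

  # two units with per-unit mean amplitudes 10 and 20
  u2 <- unit_record("b", data.frame(time_s = 1:10,
                                    amplitude_pa = rep(20, 10), selected = 1L))
  g2 <- summarize_group(list(u, u2))
  row <- g2$group[g2$group$measure == "mean_amplitude_t", ]
  expect_equal(row$mean, 15)
  expect_equal(row$sd, sqrt(50), tolerance = 1e-12)   # ~7.0711
  expect_equal(row$sem, 5)
  expect_equal(row$sem, row$sd / sqrt(row$n))

  # selected equals total when everything is selected
  expect_equal(g2$per_unit$mean_amplitude_s, g2$per_unit$mean_amplitude_t)

  # a unit with no events contributes missing values, excluded pairwise
  u0 <- unit_record("c", data.frame(time_s = numeric(0),
                                    amplitude_pa = numeric(0),
                                    selected = integer(0)))
  g3 <- summarize_group(list(u, u2, u0))
  expect_true(is.na(g3$per_unit$frequency_t[3]))
  expect_equal(g3$group$mean[g3$group$measure == "mean_amplitude_t"], 15)
  expect_equal(g3$group$n[g3$group$measure == "mean_amplitude_t"], 2)
})

test_that("cumulative relative histograms clip, accumulate and end at one", {
  # all values inside one bin: a single step to 1
  h <- cumulative_relative_histogram(rep(2.5, 7), 4, 0, 4)
  expect_equal(h$cum_rel_freq, c(0, 0, 1, 1))

  # ECDF oracle on a uniform grid spanning the range
  v <- seq(0, 3, length.out = 61)
  h2 <- cumulative_relative_histogram(v, 10, 0, 3)
  ec <- stats::ecdf(v)
  expect_true(all(abs(h2$cum_rel_freq - ec(h2$bin_upper)) <= 1 / length(v) + 1e-12))

  # fuzzed inputs: non-decreasing, final value exactly 1, out-of-range clipped
  set.seed(701)
  for (k in 1:10) {
    vals <- rnorm(sample(1:50, 1), sample(-5:5, 1), 3)
    h3 <- cumulative_relative_histogram(vals, sample(1:20, 1), -2, 2)
    expect_true(all(diff(h3$cum_rel_freq) >= 0))
    expect_identical(h3$cum_rel_freq[length(h3$cum_rel_freq)], 1)
  }
  expect_error(cumulative_relative_histogram(numeric(0), 10, 0, 1),
               class = "psc_format_error")
  expect_error(cumulative_relative_histogram(1:3, 10, 1, 1),
               class = "psc_format_error")
})

test_that("the two-sample K-S statistic matches an exhaustive ECDF-gap oracle", {
  expect_equal(ks_two_sample(1:5, 1:5)$statistic, 0)
  expect_equal(ks_two_sample(1:5, 1:5)$p_value, 1)
  expect_equal(ks_two_sample(1:5, 6:10)$statistic, 1)

  set.seed(702)
  for (k in 1:10) {
    x <- rnorm(5); y <- rnorm(5, 0.5)
    r <- ks_two_sample(x, y)
    pool <- c(x, y)
    d_oracle <- max(abs(stats::ecdf(x)(pool) - stats::ecdf(y)(pool)))
    expect_equal(r$statistic, d_oracle, tolerance = 1e-12)
  }
  expect_error(ks_two_sample(1, 1:5), class = "psc_format_error")
})

test_that("the pooled t-test matches the closed form and handles degeneracy", {
  r0 <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0); expect_equal(r0$p_value, 1)

  # |t| grows with the shift at fixed variance
  shifts <- c(0.5, 1, 2, 4)
  ts <- vapply(shifts, function(cc)
    abs(t_test_independent(c(1, 2, 3), c(1, 2, 3) + cc)$t), numeric(1))
  expect_true(all(diff(ts) > 0))

  # textbook pair against the hand-computed pooled-variance formula
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  r <- t_test_independent(a, b)
  sp2 <- (3 * stats::var(a) + 3 * stats::var(b)) / 6
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1/4 + 1/4))
  expect_equal(r$t, t_oracle, tolerance = 1e-12)
  expect_equal(r$df, 6)
  expect_equal(r$p_value, 2 * stats::pt(-abs(t_oracle), 6), tolerance = 1e-12)

  # zero pooled variance
  expect_equal(t_test_independent(c(1, 1), c(1, 1))$p_value, 1)
  d <- t_test_independent(c(1, 1), c(2, 2))
  expect_true(is.infinite(d$t)); expect_equal(d$p_value, 0)
  expect_error(t_test_independent(1, c(1, 2)), class = "psc_format_error")
})

test_that("one-way ANOVA matches a direct sum-of-squares oracle and F = t^2", {
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  r0 <- one_way_anova(g)
  expect_equal(r0$F, 0); expect_equal(r0$p_value, 1)

  a <- c(4.1, 5.2, 6.3, 5.5); b <- c(5.9, 6.8, 7.2, 6.1)
  r2 <- one_way_anova(list(a, b))
  tt <- t_test_independent(a, b)
  expect_equal(r2$F, tt$t^2, tolerance = 1e-12)
  expect_equal(r2$p_value, tt$p_value, tolerance = 1e-12)

  # three groups vs explicit between/within decomposition
  g3 <- list(c(1, 2, 3), c(2, 4, 5), c(6, 7, 9))
  r3 <- one_way_anova(g3)
  vals <- unlist(g3); gm <- mean(vals)
  ssb <- sum(vapply(g3, function(x) 3 * (mean(x) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g3, function(x) sum((x - mean(x))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(r3$F, f_oracle, tolerance = 1e-12)
  expect_equal(r3$p_value, stats::pf(f_oracle, 2, 6, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(one_way_anova(list(1:3)), class = "psc_format_error")
})

test_that("exports are deterministic and the HTML carries the same series", {
  root <- make_unit_tree()
  res <- load_units(find_unit_files(root, "??????_VC_#??", "excluded"))
  gs <- summarize_group(res$records)
  amp <- pool_event_values(res$records, "amplitude")
  hist <- list(amplitude = cumulative_relative_histogram(amp, 10, 0, 40))
  tests <- data.frame(test = "ks_amplitude", statistic = 0.25, df = NA,
                      p_value = 0.7)
  out <- withr::local_tempdir()
  files <- export_results(gs, hist, tests, out)
  expect_true(all(file.exists(files)))
  expect_length(readLines(file.path(out, "summary_per_unit.tsv")), 3L)

  html <- readLines(file.path(out, "cumulative_histograms.html"))
  tsv <- utils::read.table(file.path(out, "histogram_amplitude.tsv"),
                           header = TRUE)
  for (v in tsv$cum_rel_freq[c(1, nrow(tsv))])
    expect_true(any(grepl(sprintf("%.15g", v), html, fixed = TRUE)))

  # byte-identical re-export
  before <- lapply(files, readLines)
  export_results(gs, hist, tests, out)
  expect_identical(lapply(files, readLines), before)
})

test_that("pooled event values fall back to all events without a selection", {
  u <- unit_record("a", data.frame(time_s = c(1, 2, 4),
                                   amplitude_pa = c(10, 20, 30),
                                   selected = c(0L, 1L, 1L)))
  expect_equal(pool_event_values(list(u), "amplitude"), c(20, 30))
  expect_equal(pool_event_values(list(u), "iei"), 2)
  u0 <- unit_record("b", data.frame(time_s = c(1, 3),
                                    amplitude_pa = c(5, 6), selected = 0L))
  expect_equal(pool_event_values(list(u0), "amplitude"), c(5, 6))
})
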