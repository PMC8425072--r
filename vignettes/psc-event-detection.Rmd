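---
title: "Detecting spontaneous postsynaptic currents: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting spontaneous postsynaptic currents: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psctools)
```

## The measurement problem

In a voltage-clamped neuron, each spontaneous release of neurotransmitter
produces a transient postsynaptic current (PSC) riding on the holding
current. Excitatory events at typical holding potentials are negative-going
(inward) deflections of a few tens of pA lasting a few milliseconds, and the
two quantities neurophysiologists compare across conditions are the
amplitude of these events and their inter-event intervals (IEIs). Extracting
them from a noisy multi-sweep recording is the detection problem this
package addresses; everything downstream (selection, unit files, group
statistics, hypothesis tests) is bookkeeping around that core.

## The detection algorithm

`detect()` runs four steps per sweep, all deterministic:

1. **Smoothing.** A Savitzky–Golay (S–G) filter: a least-squares polynomial
   of degree `poly_order` is fitted over a moving window of
   `2 * side_points + 1` samples and evaluated at the window centre. Higher
   order smooths less; more side points smooth more. Within `side_points`
   samples of a sweep edge the window shrinks to the available samples
   (with the degree capped at window length − 1) instead of padding, so
   events near sweep boundaries remain detectable.
2. **Initial search.** The trend of the raw trace — a centred running
   median over `trend_window_s` (default 0.5 s), reflection-padded at the
   edges — estimates the holding current; the median is insensitive to
   PSC-scale transients, so single events displace it by well under 5% of
   their amplitude. Candidate peaks are local extrema of
   `smoothed − trend` in the polarity direction deviating more than
   `initial_threshold_pa` (default 3 pA) from the trend. Extrema are
   defined at the detector's event scale: a candidate valley must attain
   the minimum of its ±`min_separation_ms` (default 2 ms) window. This
   single definition ignores sub-scale noise wiggles, enforces the minimum
   candidate spacing by construction, and plays the role a
   width-parameterised multiscale peak detector plays in GUI
   electrophysiology packages.
3. **Baseline search.** From each candidate the algorithm searches
   backwards for the pre-event reversal: the nearest preceding sample that
   attains the maximum of its ±2 ms window (a first-difference sign change
   at the event scale; the scale-h second difference is necessarily ≤ 0
   there). The search is capped at `baseline_max_lookback_ms` (default
   10 ms) and never reaches past the previous candidate's peak — a
   secondary dip on an event's recovery limb therefore measures its own
   incremental amplitude, not the whole event again. If no reversal exists
   in the window (e.g. a monotone run longer than the window), the window
   edge is used.
4. **Final search.** The amplitude is the difference between the smoothed
   value at the peak and the baseline value, where the baseline value is
   capped at the trend: a noise excursion *above* the holding level cannot
   inflate an amplitude, while an event riding on the decaying tail of a
   predecessor (baseline below trend) keeps its smaller incremental
   amplitude. Events with amplitude ≥ `min_amplitude_pa` (default 10 pA;
   ties retained, configurable via `amplitude_rule`) are accepted.

Positive-going events are handled by negating the trace and reusing the
negative-going path, which makes every stage exactly polarity-symmetric
(`detect(-x, positive)` mirrors `detect(x, negative)` bit for bit).

### Why the baseline is capped at the trend

The cap is the single most consequential design choice, so it is exposed as
`detection_params(baseline_cap = "trend" | "none")`. With `"none"`, the
amplitude of a pure-noise candidate is the span from a noise bump top to a
noise dip bottom — two ~3σ excursions combine, and at a smoothed-noise SD
of ~2 pA the 10 pA criterion is crossed thousands of times in a 250-s
trace. Measured on the simulated benchmark below (σ = 6 pA, poly 3, side
points 7) the uncapped rule yields F1 ≈ 0.06 versus ≈ 0.96 capped, at
identical recall. The cap makes a noise candidate's amplitude a one-sided
tail statistic (its depth below the holding level), which is what keeps
false positives rare at practical criteria.

A consequence worth knowing: because amplitudes are then robust to noise at
the baseline, the best-case mean detected amplitude in a noisy recording
stays close to the true mean (the residual bias is the argmin selection at
the peak, of order +0.5–0.8 smoothed-noise SD, against S–G attenuation).
Detector families whose baseline search stops at raw-trace reversals report
substantially attenuated best-case amplitudes under identical settings;
comparisons of absolute amplitude scales across tools should account for
this measurement-rule difference.

### Savitzky–Golay behaviour worth knowing

* The filter reproduces any polynomial up to `poly_order` exactly (interior
  points), which the tests assert to 1e-9.
* On a biexponential event the cubic fit slightly *overshoots* the valley
  (≤ ~2%) while the half-window is below the event's core (~1.5 ms at the
  default kinetics); beyond that, attenuation grows monotonically with the
  window. The measured amplitude of a clean 30 pA event falls by ~25% by
  side points 50 at 10 kHz.
* Because the kernel is asymmetric (fast rise, slow decay), smoothing
  shifts the extremum slightly late — about 2 samples at side points 14 —
  which is negligible against the 5 ms matching tolerance used in scoring.

## The simulated benchmark

`simulate_recording()` builds the validation benchmark: `n_events = 250`
biexponential quantal-conductance events placed uniformly at random in a
`duration_s = 250` s, 10 kHz, zero-baseline single sweep, with
`add_noise()` overlaying white Gaussian noise of SD 2, 6 or 10 pA. The
kernel is

$$g(t) = \frac{A}{A'}\left[-e^{-t/\tau_1} + e^{-t/\tau_2}\right],\quad t > 0
\qquad A' = \frac{\tau_2^{\,\tau_1/(\tau_1-\tau_2)}}{\tau_1},$$

with defaults $A = -12.783$ nS, $\tau_1 = 0.5$ ms, $\tau_2 = 3$ ms; the
peak occurs at $t^\* = \tau_1\tau_2/(\tau_2-\tau_1)\,\ln(\tau_2/\tau_1)
\approx 1.075$ ms. The printed branch condition is implemented causally
(nonzero for $t > 0$), and $A'$ is evaluated once at the nominal time
constants.

Design choices a user may want to revisit:

* **Kinetic jitter.** Each event's $\tau_1$ and $\tau_2$ are multiplied by
  a normal draw (mean 1, SD 0.3; draws ≤ 0.1, or violating
  $\tau_2 > \tau_1$, are resampled). By default one draw is **shared** by
  both constants (`tau_jitter = "shared"`), which varies the kinetics while
  leaving every analytic peak amplitude at the calibrated value — under a
  fixed normalisation, a common factor only rescales time. This makes the
  amplitude distribution degenerate by construction, which is what lets a
  minimum-amplitude criterion well below the calibrated mean operate with
  essentially no misses, and it pins the benchmark's behaviour to noise
  rather than to an arbitrary amplitude spread. `tau_jitter =
  "independent"` draws separately for the two constants; the peaks then
  disperse (SD ≈ 5.8 pA at the default calibration) and a tail of
  genuinely small events appears, which is the more demanding — but less
  controlled — benchmark.
* **Amplitude calibration.** The conductance-to-current conversion is one
  global constant chosen so the mean true peak is
  `amp_calibration_mean_pa = 27.85` pA. Every ratio reported by the
  harness (attenuation, restoration) is invariant to this constant.
* **What the generator does not emulate.** Correlated (1/f or line) noise,
  series-resistance filtering, baseline drift during an event, bursting
  IEI statistics, and overlapping-event pile-up beyond chance coincidence.
  Detector scores on this benchmark therefore bound performance from
  above; real recordings degrade gracefully mainly through the trend
  estimate (drift) and the noise spectrum.

`match_events()` scores a detection one-to-one against ground truth by
greedy ascending time difference within 5 ms (equal to optimal assignment
when events are separated, which the tests verify by brute force);
`precision_recall_f1()` derives the metrics, with the convention that a
0/0 ratio is missing and F1 = 0 when no true positive exists. True
negatives — 1-s grid segments containing no peaks at all — are reported for
completeness and never enter F1. `parameter_sweep()` repeats
detect-match-score over a grid of smoothing settings, sharing the trend
(a property of the raw trace) and the candidate pass across
minimum-amplitude values, which is exactly equivalent to separate
`detect()` runs by the monotone-threshold property.

## The retrieval layer

Unit files — three tab-separated columns per event: absolute peak time (s),
amplitude (pA), selection flag — are the interchange format between
detection and batch analysis. Times are stored as absolute (sweep offset +
in-sweep time) so IEIs can be computed across a whole recording from the
file alone. `find_unit_files()` matches base names case-insensitively with
`?` as the single-character wildcard (no `*`), skipping excluded folder
names at any depth. Per-unit frequency is defined as event count divided by
the time of the last event, since the unit file does not persist the
recording duration; supply your own duration if you prefer by dividing
counts yourself. Group statistics use the sample SD (n − 1) and
SEM = SD/√n over per-unit values, excluding empty units pairwise.

Cumulative relative histograms clip out-of-range values into the end bins
so the curve always ends at exactly 1. The K–S test compares pooled
event-level values (selected events) with the asymptotic p-value; the
t-test is the pooled-variance Student variant (Welch available via
`var_equal = FALSE`); the one-way ANOVA reduces exactly to t² for two
groups. No multiple-testing correction is applied. Degenerate inputs
(zero variance) return t = 0/p = 1 on equal means and an infinite-statistic
guard otherwise, rather than erroring mid-batch.

## Numerical and testing notes

* Problem sizes: the full 250-event benchmark is used for the
  benchmark-level tests (a single detect pass over 2.5 M samples takes a
  few seconds); unit tests use 12–60-event benchmarks and closed-form
  fixtures. The full side-points 2–50 sweep is exercised in the
  reproduction script; tests sample the grid.
* Decay fits (`fit_decay()`) use explicit starting values (asymptote from
  the window tail, rate from a log-linear fit) refined by
  Levenberg–Marquardt, because self-starting Gauss–Newton stalls on
  zero-residual windows. Fits are flagged, never silently zero; τ outside
  (0, 1000] ms is a failure.
* Ties: flat valley bottoms yield tied window minima; the earliest sample
  wins. Exact float ties are the only way two candidates can sit within
  the separation window.
* The trend estimator shortens its window to the trace length (odd) for
  very short sweeps, and `estimate_trend` is exactly equivariant to adding
  a constant.
* Seeds: every stochastic step (placement, jitter, noise) takes an explicit
  seed; the whole pipeline is a pure function of (config, kernel, detector
  params, seeds).

## Known limitations

* The detector is threshold-based, not template- or deconvolution-based;
  heavily overlapping events within ~2 ms merge into one candidate by
  construction, and a truth event lost that way is scored as a miss.
* Amplitudes are measured on the smoothed trace, so they attenuate with
  the smoothing window; compare amplitudes only at fixed smoothing
  settings.
* ABF/DAT binary import is not implemented; export sweeps as tab-delimited
  text (column-wise, unit A or pA) from the acquisition software.
* The K–S p-value is asymptotic; for very small pooled samples an exact
  test may be preferable.
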