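---
title: "Methods: quantifying echo-kinetic responses from biologging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying echo-kinetic responses from biologging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echokin)
```

## The problem

Echolocating toothed whales sample their surroundings with discrete clicks.
The inter-click interval (ICI) sets the maximum unambiguous sensing range —
the *acoustic depth of field*, ICI × c/2 (3.75 m for a 5 ms ICI at
c = 1500 m/s). During prey-capture buzzes, porpoises click every ~2.5 ms; a
prey fish that bolts can leave the depth of field within tens of
milliseconds, so the animal must re-expand its ICI to keep ranging
unambiguous. The speed of that adjustment — the echo-kinetic response
latency — tells us whether echo information is processed click-by-click or
integrated over many clicks.

`echokin` implements the measurement chain for this question: click and
buzz detection in tag audio, echogram formation and echo-trace extraction,
event-locked statistics of ICI changes and body jerk against bootstrap
nulls, and latency estimation by threshold crossings and by collapsing the
hysteresis loops between prey range and depth of field.

## The synthetic trial generator

Real tag data require manual curation; the package instead validates every
stage against a simulator with known ground truth, `simulate_trial()`. A
trial emulates a captive-style target approach:

* **Geometry.** The predator closes at `closing_speed` (default 1 m/s)
  from `initial_range` (2.8 m). At `event_time` the target escapes and the
  range *opens* at `escape_speed_excess` (the amount by which the escape
  speed exceeds the closing speed), producing the characteristic V-shaped
  echo trace. Trials selected for timing analysis in practice require this
  excess to exceed 0.25 m/s; the simulator default of 1 m/s represents a
  clear escape.
* **ICI control law.** Clicks are emitted iteratively with
  `ICI(t) = m · 2 r(t − L) / c`, where `m` is a safety margin
  (`ici_margin_factor`, default 1.4, chosen so that the ICI at a 1.3 m
  range is ~2.4 ms, matching reported porpoise buzz ICIs) and `L` is the
  pure transport delay under study (`response_latency`). The ICI is
  clamped to the species buzz range (2–13 ms for the porpoise preset,
  3.5–100 ms for the beaked-whale preset) and multiplied by lognormal-like
  jitter (`ici_jitter`, default 2% s.d.) emulating routine ICI variation.
  The functional form of the wild control law is not known; the
  proportional-margin form is this package's choice and only its delay
  structure is exploited by the estimators.
* **Saccades.** With `saccade_enabled`, the commanded ICI ramps to
  `saccade_boost` (1.5) times the tracking law with time constant
  `saccade_tau` (50 ms) once the escape is perceived, emulating the
  ballistic, over-compensating depth-of-field expansions seen during real
  chases. The ramp makes successive ICI changes strongly positive, which
  is what the event-locked δICI statistic detects.
* **Audio.** Clicks are Gaussian-windowed tone bursts at the species
  centre frequency (130 kHz / ~10 cycles for `pp`; 40 kHz / ~40 µs for
  `md`), with ≥95% of their energy in the species analysis band. Each
  click is followed by a target echo delayed by 2r/c (exact to one audio
  sample) and attenuated by two-way spherical spreading (40 log10 r);
  constant target strength, no absorption (negligible below 10 m). Noise
  is white Gaussian; `echo_snr_at_1m` (default 30 dB) sets the echo-to-
  noise ratio on the echogram scale at 1 m, and `click_snr_db` (40 dB)
  the level of the outgoing clicks. `echo_snr_at_1m = Inf` renders a
  noiseless trial with the 1 m echo fixed 20 dB below the click.
* **Motion.** The body accelerometer carries gravity, a 2 Hz swimming
  stroke, sensor noise, and — `response_latency_jerk` after the event — a
  damped 10 Hz burst whose peak norm-jerk is `jerk_peak` (500 m/s³,
  comfortably above the 300 m/s³ detection threshold for the 10 ms RMS
  detector; note that a burst starting mid-bin needs a peak near
  700–800 m/s³ before a 50 ms *bin* RMS exceeds 300). The two-axis target
  accelerometer carries small constant gravity offsets (its axes are
  nominally horizontal) and an acceleration burst at the event itself.

Identical configurations (including `seed`) produce identical bundles.

What the simulator does **not** emulate: multipath (surface/bottom
echoes), schooling prey, beam patterns, click-level amplitude variation,
non-Gaussian or coloured noise, and predator strikes that confound wild
kinematic responses. Passing tests therefore demonstrate correctness of
the estimators under the stated statistical structure, not performance on
raw field recordings, which additionally need the quality screening that
`extract_trace()`'s validity flags only partially automate.

## Click detection and buzzes

`detect_clicks()` is an automated stand-in for supervised click audits.
The band-limited Hilbert envelope is compared against a running noise
floor (median over 50 ms blocks, scaled by 1/sqrt(ln 2) to the
RMS-equivalent of a Rayleigh envelope); local maxima more than `thresh_db`
(15 dB) above the floor are accepted greedily in amplitude order subject
to a blanking interval (half the species' minimum buzz ICI), and a
relative gate (12 dB below the 90th-percentile peak) rejects target
echoes, which at sub-metre ranges can exceed the absolute threshold but
remain far weaker than the outgoing clicks recorded on-animal. The gate
is the detector's main idealisation: below ~0.7 m target range, echoes
approach click level and the detector is not validated there. On
simulated audio with ≥20 dB click SNR, detections are within ±50 µs of
the true emission times.

Buzzes follow the species definition: maximal runs of ICIs below 13 ms
(`pp`) or 100 ms (`md`) whose first-to-last-click span is at least 0.5 s.
The span convention (not padded by the surrounding ICIs) is this
package's choice; the definition's source is silent on the endpoint.

## Echograms and traces

`form_echogram()` bandpass-filters (4th-order Butterworth, applied
forward and backward so click and echo timing is unbiased), takes the
Hilbert envelope, block-averages it to ~96 kHz (`pp`) / 48 kHz (`md`)
— sub-centimetre range bins of c/(2 f_env) — and cuts one segment per
click, mapped to range by r = c·τ/2. SNR is referenced to the median
envelope over the last 20% of each click's own segment. Block averaging
also caps noise-only SNR excursions near ~10 dB, which motivates the
12 dB default quality threshold in `extract_trace()`.

`extract_trace()` tracks the highest-SNR peak within a gate (0.5 m)
centred on the last valid range, refining peaks by parabolic
interpolation. Ranges below 0.2 m (transmit tail) and beyond the click's
unambiguous range (where the *next* outgoing click appears — the
"depth-of-field line" of real echograms) are masked. Clicks with no peak
at or above `min_snr` are flagged invalid rather than guessed.

`detect_motion_onset()` replaces manual V-apex picking: a two-segment
piecewise-linear fit over the valid trace, break at the residual-minimising
split, event time at the intersection of the fitted lines. An event is
only reported when the slope increases by more than 0.25 m/s (the escape
selection criterion); on clean V traces the apex is recovered well within
the ±10 ms accuracy attributed to manual picking.

## Event-locked statistics and the bootstrap null

`delta_ici_proportions()` bins the sign of consecutive ICI changes into
50 ms (`pp`) or 100 ms (`md`) bins spanning ±500 ms around the event.
Each change is assigned to the emission time of the later click involved
— the change is only observable once that click is produced — and zero
changes count as non-positive. `jerk_rms_bins()` does the analogous
binning of RMS norm-jerk (first differences scaled by the sampling rate;
no smoothing, since smoothing biases latencies).

`bootstrap_null()` implements the buzz-pair randomisation: each replicate
transplants the buzz-start-to-event offset of a randomly drawn partner
onto every trial, recomputes the statistic at the mock event, aggregates
across trials, and flags bins where the observed aggregate exceeds more
than 95% of replicates (ties counted one half). Two aggregates are
provided. The default **pools counts across trials** (total positive
changes / total changes per bin); the **median** of per-trial proportions
is available as an option. Pooling is the default because calibration
demands it: per-trial bin proportions are ratios of roughly ten counts
whose support always contains 0.5, so the null distribution of their
median carries a large atom at 0.5 that an observed median can rarely
exceed — in simulation the median aggregate yields a per-bin
false-positive rate of ~0.02–0.03 at the nominal 0.05, while the pooled
aggregate is calibrated at 0.050 (a control experiment with continuous
exchangeable statistics confirms the testing machinery itself is exact).
Significance is per-bin at the 95% criterion, uncorrected for multiple
bins, matching the original analysis convention.

## Latency estimators

* `threshold_latency_ici()`: time from the event to the first post-event
  click whose forward ICI exceeds 5 ms (depth of field beyond 3.75 m) —
  the onset of a *strong* outward adjustment. Pre-event crossings are
  ignored.
* `threshold_latency_jerk()`: first post-event crossing of 300 m/s³ by
  the RMS norm-jerk over a 10 ms sliding window (centred; the window
  length is this package's choice for the "RMS jerk" of the threshold
  definition).
* `loop_area_latency()`: plots prey range against depth of field,
  advances the depth-of-field series in 5 ms steps (0–300 ms), and
  returns the advance minimising the absolute shoelace area of the closed
  trajectory polygon. Both series are linearly interpolated to a common
  200 Hz base (the click series is denser; 200 Hz resolves the 5 ms grid
  without aliasing the slower trace), and every advance is scored over
  the same evaluation window so the comparison is not confounded by
  overlap length — total area, not per-loop areas, is minimised. Ties go
  to the smallest advance; with a single loop the absolute net shoelace
  sum equals the enclosed area, and same-orientation loops add.
  `estimate_loop_latency()` wraps the full pipeline and applies a
  3-point running median to the extracted ranges to suppress isolated
  mis-gated clicks.
* `rms_target_acceleration()`: gravity removed as per-axis means over a
  1 s pre-onset baseline, onset at the first excursion beyond 5 baseline
  standard deviations, cue = RMS of the summed squared axes over the
  following 0.5 s.
* `inverse_latency_regression()`: OLS of 1/latency on the cue, the
  reciprocal linearising the latency–cue relationship; with zero variance
  in 1/latency the slope and r² are reported as 0 with p = 1.

## Numerical choices and degenerate inputs

Envelope computation pads to a fast FFT length. The loop estimator
requires a non-degenerate range series and a common support of at least
twice the maximum advance, and errors otherwise. Trace extraction signals
an empty trace (all clicks invalid) rather than erroring; onset and
threshold estimators return `NULL` as their "no event / no crossing /
no cue" signal. WAV I/O shares a single 1/32768 scale so write–read
cycles are idempotent after the first quantisation.

## Problem sizes used in validation

The packaged checks run: loop-delay recovery at injected latencies of
30–150 ms with 20 trials per latency, noiseless (tolerance one 5 ms grid
step) and at 15 dB trace SNR (two grid steps; encoded as a 34 dB echo SNR
at 1 m so the echo is ~15 dB above noise at the trial's ~3 m maximum
range); bootstrap calibration over 100 independent 30-trial null cohorts
with 200 replicates each; and a 30-trial strong-response cohort
(75 ms latency) whose first significant δICI bin is expected at
50–100 ms. Trials are 2.5 s at the porpoise tag rate of 576 kHz.

## Known limitations

Single-target tracking only; one event per simulated trial (repeated
escapes are exercised at the series level, not rendered in audio); the
automated detector and onset picker are validated on synthetic data only;
significance is per-bin and uncorrected; the regression pools animals
(no grouping term), with per-animal analysis left to the caller.
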