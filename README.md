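# echokin

Analysis of the sensor-motor feedback loop in toothed whale echolocation
from sound-and-movement biologging tags.

Echolocating toothed whales probe their surroundings with discrete clicks.
The inter-click interval (ICI) fixes the maximum unambiguous sensing range
— the *acoustic depth of field*, ICI × c/2, e.g. 3.75 m at a 5 ms ICI for
c = 1500 m/s. During prey-capture buzzes, porpoises click every ~2.5 ms;
when a prey fish bolts, the predator must rapidly re-expand its ICI to keep
the target inside the depth of field. The latency of that adjustment — the
*echo-kinetic response* — reveals whether echoes are processed
click-by-click or integrated over many clicks: a response latency of
~100 ms spanning ≥20 clicks implies the information bandwidth 1/(2·ICI)
exceeds the feedback control bandwidth ~1/(4·latency) roughly 40-fold.

`echokin` provides the complete measurement chain:

* **Trial I/O** — per-trial bundles (WAV audio + CSV accelerometry + JSON
  metadata) with validation (`read_trial_bundle()`, `write_trial_bundle()`).
* **Click & buzz detection** — envelope-based click detection with ±50 µs
  timing on clean audio, forward-ICI series, species-specific buzz
  segmentation (ICI < 13 ms for harbour porpoise, < 100 ms for Blainville's
  beaked whale, sustained ≥ 0.5 s).
* **Echograms** — per-click range-mapped envelope stacks (`form_echogram()`),
  gated echo-trace extraction (`extract_trace()`), and automatic V-apex /
  slope-change detection (`detect_motion_onset()`).
* **Event-locked statistics** — proportions of positive ICI changes and RMS
  jerk in 50/100 ms bins around the prey movement, with a buzz-pair
  bootstrap null and per-bin 95% significance (`bootstrap_null()`).
* **Latency estimation** — ICI (5 ms) and jerk (300 m/s³) threshold
  crossings, loop-area minimisation between prey range and depth of field
  (`loop_area_latency()`), RMS target-acceleration cues and the
  inverse-latency regression.
* **Synthetic trials** — a generator with ground-truth click times, ranges
  and injected latencies (`simulate_trial()`), used to validate every
  estimator end to end.

## Worked example

Simulate a porpoise approaching a target that escapes at t = 1.4 s, with a
90 ms ICI control delay, then recover that delay from the rendered audio
alone:

```r
library(echokin)

cfg   <- sim_config(response_latency = 0.09, ici_jitter = 0.01,
                    echo_snr_at_1m = 34, seed = 42)
trial <- simulate_trial(cfg)
trial
#> <trial_bundle> sim [pp] 2.50 s audio @ 576 kHz, accel @ 200 Hz, target accel, event @ 1.400 s, ground truth

res <- process_trial(trial)     # clicks -> echogram -> echo trace
res$train
#> <click_train> 679 clicks, ICI 2.61-5.46 ms (median 3.58)

segment_buzzes(res$train, "pp")[, c("start_time", "end_time", "duration")]
#>    start_time end_time duration
#> 1 0.002697917 2.496406 2.493708

detect_motion_onset(res$trace)  # the target escape, from the echo trace
#> <motion_event> v_apex at 1.400 s (slope -1.00 -> 1.00 m/s)

estimate_loop_latency(trial)    # advance that collapses the range/DOF loops
#> <latency_estimate> loop_area: 0.095 s
```

The whole 2.5 s record is one buzz (all ICIs below 13 ms for more than
0.5 s). The escape is located at the V-apex of the echo trace to within a
few milliseconds, and advancing the depth-of-field series in 5 ms steps
until the hysteresis loops collapse recovers the injected 90 ms delay to
within one grid step at this echo SNR (~15 dB at the trial's maximum
range); noiseless trials recover it exactly. `plot(res$echogram)` draws
the echogram with the target trace and the depth-of-field line.

A thin command-line wrapper covers the same pipeline
(`inst/exec/echokin sim|io|clicks|trace|respond|latency`).

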