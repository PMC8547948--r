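# Shared fixtures for the test suite. Everything is generated in code;
# trial durations are kept short so the full audio pipeline stays fast.

# short porpoise approach: closing 1 m/s from 2 m, escape at 0.7 s
short_cfg <- function(...) {
  args <- modifyList(list(duration = 1.2, initial_range = 2.0,
                          closing_speed = 1.0, event_time = 0.7,
                          escape_speed_excess = 1.0, seed = 11L),
                     list(...))
  do.call(sim_config, args)
}

# base configuration for statistic cohorts (click trains only)
cohort_cfg <- function(...) {
  args <- modifyList(list(duration = 2.5, initial_range = 2.8,
                          closing_speed = 0.8, event_time = 1.2,
                          ici_jitter = 0.02), list(...))
  do.call(sim_config, args)
}

# audio containing the pp click template at given times in Gaussian noise;
# env_snr is the template-peak to envelope-noise-RMS ratio in dB
template_audio <- function(times, fs = 576e3, duration = NULL, env_snr = 30,
                           amps = 1, seed = 1L) {
  set.seed(seed)
  if (is.null(duration)) duration <- max(times) + 0.02
  tpl <- make_click_waveform("pp", fs)
  n <- round(duration * fs)
  bw_frac <- diff(species_preset("pp")$band) / (fs / 2)
  sigma <- if (is.finite(env_snr)) {
    10^(-env_snr / 20) / sqrt(2) / sqrt(bw_frac)
  } else 0
  x <- rnorm(n, sd = sigma)
  amps <- rep_len(amps, length(times))
  peak <- which.max(abs(tpl))
  for (k in seq_along(times)) {
    i0 <- round(times[k] * fs) + 1L - (peak - 1L)
    idx <- i0:(i0 + length(tpl) - 1L)
    ok <- idx >= 1L & idx <= n
    x[idx[ok]] <- x[idx[ok]] + amps[k] * tpl[ok]
  }
  audio_stream(x, fs)
}

# a clean synthetic echo trace (data.frame in echo_trace form)
synthetic_trace <- function(t, r, snr = 20) {
  data.frame(click_time = t, range = r, snr = snr, valid = TRUE)
}
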