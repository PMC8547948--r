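# Synthetic trial generator. Emulates the geometry and control structure of
# a close prey approach: a predator closing at ~1 m/s on a target that makes
# a sudden escape at event_time, an ICI control law that tracks the two-way
# travel time with a pure transport delay, echoes in noise, and a jerk
# transient on the body accelerometer a fixed delay after the event.

#' Simulation configuration
#'
#' Assembles and validates the parameter set for [simulate_trial()]. The
#' defaults describe a harbour-porpoise-style captive trial: closing at
#' 1 m/s from 2.8 m, a target escape at 1.4 s opening range at 1 m/s, a
#' 90 ms ICI response delay and a 50 ms kinematic response delay.
#'
#' @param duration record length, s.
#' @param species_preset `"pp"` or `"md"`.
#' @param fs_audio audio sampling rate, Hz (default from the preset).
#' @param fs_accel accelerometer rate, Hz (default from the preset).
#' @param initial_range predator-target range at t = 0, m.
#' @param closing_speed pre-event closing speed, m/s (positive = closing).
#' @param event_time time of the target escape, s; must lie in
#'   `(0, duration)`.
#' @param escape_speed_excess amount by which the target escape speed
#'   exceeds the closing speed, m/s (>= 0); after the event the range opens
#'   at this net rate. 0 gives no escape.
#' @param response_latency pure delay of the ICI control loop, s.
#' @param response_latency_jerk delay from event to the body jerk
#'   transient, s.
#' @param ici_margin_factor safety margin of the control law: target ICI =
#'   margin x two-way travel time; must be > 1.
#' @param ici_jitter multiplicative ICI noise (s.d. as a fraction of the
#'   commanded ICI); emulates the routine ICI variation of real buzzes.
#' @param saccade_enabled if `TRUE`, the first clicks after the delayed
#'   escape perception get a ballistic over-compensating ICI boost.
#' @param saccade_boost peak multiplicative boost of the saccade.
#' @param saccade_tau time constant of the saccadic ramp, s; the boost
#'   saturates within a few tau of the delayed escape perception.
#' @param echo_snr_at_1m echo SNR at 1 m range on the echogram scale, dB;
#'   `Inf` renders a noiseless trial. Echo level falls with two-way
#'   spherical spreading (40 log10 r).
#' @param click_snr_db SNR of the outgoing clicks themselves, dB.
#' @param jerk_peak peak norm-jerk of the body response transient, m/s^3.
#' @param target_accel_peak peak acceleration of the target movement cue on
#'   the target accelerometer, m/s^2.
#' @param sound_speed m/s; 1500 m/s makes a 5 ms ICI correspond to a
#'   3.75 m depth of field.
#' @param seed integer RNG seed; identical configs give identical bundles.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration = 2.5,
                       species_preset = "pp",
                       fs_audio = NULL,
                       fs_accel = NULL,
                       initial_range = 2.8,
                       closing_speed = 1.0,
                       event_time = 1.4,
                       escape_speed_excess = 1.0,
                       response_latency = 0.09,
                       response_latency_jerk = 0.05,
                       ici_margin_factor = 1.4,
                       ici_jitter = 0.02,
                       saccade_enabled = FALSE,
                       saccade_boost = 1.5,
                       saccade_tau = 0.05,
                       echo_snr_at_1m = 30,
                       click_snr_db = 40,
                       jerk_peak = 500,
                       target_accel_peak = 5,
                       sound_speed = 1500,
                       seed = 1L) {
  sp <- species_preset(species_preset)
  if (is.null(fs_audio)) fs_audio <- sp$fs_audio
  if (is.null(fs_accel)) fs_accel <- sp$fs_accel
  cfg <- list(duration = duration, species_preset = sp$name,
              fs_audio = fs_audio, fs_accel = fs_accel,
              initial_range = initial_range, closing_speed = closing_speed,
              event_time = event_time,
              escape_speed_excess = escape_speed_excess,
              response_latency = response_latency,
              response_latency_jerk = response_latency_jerk,
              ici_margin_factor = ici_margin_factor,
              ici_jitter = ici_jitter,
              saccade_enabled = saccade_enabled,
              saccade_boost = saccade_boost,
              saccade_tau = saccade_tau,
              echo_snr_at_1m = echo_snr_at_1m,
              click_snr_db = click_snr_db,
              jerk_peak = jerk_peak,
              target_accel_peak = target_accel_peak,
              sound_speed = sound_speed, seed = as.integer(seed))
  validate_sim_config(cfg, sp)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg, sp = species_preset(cfg$species_preset)) {
  if (!(cfg$duration > cfg$event_time && cfg$event_time > 0))
    stop("validation error: need duration > event_time > 0")
  if (cfg$fs_audio < 4 * sp$click_centre)
    stop("validation error: fs_audio must be >= 4x the click centre frequency")
  if (cfg$ici_margin_factor <= 1)
    stop("validation error: ici_margin_factor must be > 1")
  if (cfg$escape_speed_excess < 0)
    stop("validation error: escape_speed_excess must be >= 0")
  range_end <- if (cfg$escape_speed_excess > 0) cfg$event_time else cfg$duration
  min_range <- cfg$initial_range - cfg$closing_speed * range_end
  if (min_range <= 0.25)
    stop("validation error: prey range must stay positive (> 0.25 m) over the record")
  invisible(TRUE)
}

#' Ground-truth prey range at given times
#'
#' Range follows a constant closing speed until the event, then opens at
#' `escape_speed_excess` (the piecewise-linear "V" of an evasive target).
#'
#' @param truth a ground-truth list (from [simulate_trial()] or a
#'   bundle's `ground_truth` field) or a `sim_config`.
#' @param t numeric vector of times, s.
#' @return numeric vector of ranges, m.
#' @export
prey_range <- function(truth, t) {
  r <- truth$initial_range - truth$closing_speed * pmin(t, truth$event_time)
  post <- t > truth$event_time
  if (truth$escape_speed_excess > 0 && any(post)) {
    r[post] <- r[post] + truth$escape_speed_excess * (t[post] - truth$event_time)
  } else if (any(post)) {
    # no escape (null trial): range keeps closing at constant speed
    r[post] <- truth$initial_range - truth$closing_speed * t[post]
  }
  r
}

#' Species click waveform template
#'
#' A Gaussian-windowed tone burst at the species' click centre frequency,
#' with unit peak amplitude, whose energy lies essentially inside the
#' species analysis band (a narrowband ~10-cycle pulse near 130 kHz for the
#' porpoise preset; a shorter ~40 us transient near 40 kHz for the beaked
#' whale preset).
#'
#' @param preset `"pp"` or `"md"`.
#' @param fs sampling rate, Hz; must be at least 4x the centre frequency.
#' @return numeric vector, the pressure template (unit peak).
#' @export
make_click_waveform <- function(preset = "pp", fs = NULL) {
  sp <- species_preset(preset)
  if (is.null(fs)) fs <- sp$fs_audio
  if (fs < 4 * sp$click_centre)
    stop("aliasing error: fs must be >= 4x the click centre frequency (",
         4 * sp$click_centre, " Hz)")
  f0 <- sp$click_centre
  sigma_t <- sp$click_cycles / f0 / 4     # ~n_cycles total duration (4 sigma)
  half <- ceiling(3 * sigma_t * fs)
  t <- (-half:half) / fs
  w <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
  w / max(abs(w))
}

# Commanded ICI at absolute time t: margin x two-way travel time to the
# delayed range, clamped to the species buzz ICI range.
control_law_ici <- function(t, cfg, sp) {
  r <- prey_range(cfg, t - cfg$response_latency)
  ici <- cfg$ici_margin_factor * 2 * r / cfg$sound_speed
  pmin(pmax(ici, sp$ici_min), sp$buzz_ici_max)
}

#' Generate the ground-truth click train of a trial
#'
#' Runs the ICI control law alone (no audio rendering): clicks are emitted
#' iteratively with ICI = `ici_margin_factor` x the two-way travel time to
#' the target range as it was `response_latency` seconds ago, clamped to
#' the species buzz ICI range, with optional multiplicative jitter and an
#' optional saccadic over-compensation boost after the (delayed) escape.
#' Useful for response-statistic cohorts where the audio path is not under
#' test.
#'
#' @param config a [sim_config()].
#' @return list with `times` (click emission times, s), `ici` (forward
#'   intervals), `truth` (ground-truth list as in [simulate_trial()]).
#' @export
simulate_click_train <- function(config) {
  cfg <- config
  sp <- species_preset(cfg$species_preset)
  validate_sim_config(cfg, sp)
  set.seed(cfg$seed)
  t_resp <- cfg$event_time + cfg$response_latency
  times <- numeric(0)
  t <- control_law_ici(0, cfg, sp) / 2   # first click shortly after t = 0
  while (t < cfg$duration) {
    times <- c(times, t)
    ici <- control_law_ici(t, cfg, sp)
    if (cfg$saccade_enabled && cfg$escape_speed_excess > 0 && t >= t_resp) {
      # ballistic over-compensation: the commanded ICI ramps up to
      # saccade_boost x the tracking law within a few saccade_tau and stays
      # expanded, extending the depth of field well beyond the escaping target
      tau <- if (is.null(cfg$saccade_tau)) 0.05 else cfg$saccade_tau
      boost <- 1 + (cfg$saccade_boost - 1) * (1 - exp(-(t - t_resp) / tau))
      ici <- ici * boost
    }
    if (cfg$ici_jitter > 0) ici <- ici * (1 + cfg$ici_jitter * rnorm(1))
    ici <- max(ici, sp$ici_min / 2)       # jitter must not reverse time
    t <- t + ici
  }
  truth <- list(
    event_time = cfg$event_time,
    response_latency_ici = cfg$response_latency,
    response_latency_jerk = cfg$response_latency_jerk,
    initial_range = cfg$initial_range,
    closing_speed = cfg$closing_speed,
    closing_speed_pre = cfg$closing_speed,
    escape_speed_excess = cfg$escape_speed_excess,
    sound_speed = cfg$sound_speed,
    click_times = times
  )
  list(times = times, ici = diff(times), truth = truth)
}

render_audio <- function(cfg, sp, click_times) {
  n <- round(cfg$duration * cfg$fs_audio)
  tpl <- make_click_waveform(cfg$species_preset, cfg$fs_audio)
  half <- (length(tpl) - 1L) %/% 2L
  peak_idx <- which.max(abs(tpl))
  bw_frac <- diff(sp$band) / (cfg$fs_audio / 2)
  env_noise_rms <- 10^(-cfg$click_snr_db / 20)       # in-band envelope RMS
  if (is.finite(cfg$echo_snr_at_1m)) {
    x <- rnorm(n, sd = env_noise_rms / sqrt(2) / sqrt(bw_frac))
    a1 <- env_noise_rms * 10^(cfg$echo_snr_at_1m / 20)
  } else {
    # noiseless trial: no noise is rendered, so "SNR" is unbounded; keep the
    # physical level model by fixing the 1 m echo 20 dB below the click
    x <- numeric(n)
    a1 <- 0.1
  }
  ranges <- prey_range(cfg, click_times)
  delays <- 2 * ranges / cfg$sound_speed
  tpl_len <- length(tpl)
  for (k in seq_along(click_times)) {
    ci <- round(click_times[k] * cfg$fs_audio) + 1L
    ei <- ci + round(delays[k] * cfg$fs_audio)
    for (p in 1:2) {
      i0 <- (if (p == 1L) ci else ei) - (peak_idx - 1L)
      amp <- if (p == 1L) 1.0 else a1 / ranges[k]^2
      lo <- max(1L, i0); hi <- min(n, i0 + tpl_len - 1L)
      if (lo <= hi) x[lo:hi] <- x[lo:hi] + amp * tpl[(lo - i0 + 1L):(hi - i0 + 1L)]
    }
  }
  # headroom so 16-bit round trips are exact to 1 LSB
  audio_stream(x / 1.25, cfg$fs_audio)
}

damped_burst <- function(t, t0, peak_rate, f = 10, tau = 0.15) {
  # acceleration whose first derivative (jerk) peaks at peak_rate
  amp <- peak_rate / (2 * pi * f)
  out <- numeric(length(t))
  on <- t >= t0
  out[on] <- amp * sin(2 * pi * f * (t[on] - t0)) * exp(-(t[on] - t0) / tau)
  out
}

render_body_motion <- function(cfg) {
  t <- seq(0, cfg$duration - 1 / cfg$fs_accel, by = 1 / cfg$fs_accel)
  stroke <- 0.5 * sin(2 * pi * 2 * t)                  # slow swimming stroke
  noise_sd <- 0.02
  a <- cbind(ax = stroke + rnorm(length(t), sd = noise_sd),
             ay = rnorm(length(t), sd = noise_sd),
             az = 9.81 + rnorm(length(t), sd = noise_sd))
  if (cfg$escape_speed_excess > 0 && cfg$jerk_peak > 0) {
    t0 <- cfg$event_time + cfg$response_latency_jerk
    a[, 1] <- a[, 1] + damped_burst(t, t0, cfg$jerk_peak)
  }
  sensor_stream(a, cfg$fs_accel, axes = 3L)
}

render_target_motion <- function(cfg) {
  t <- seq(0, cfg$duration - 1 / cfg$fs_accel, by = 1 / cfg$fs_accel)
  g <- c(0.3, -0.2)                                     # small gravity leak,
  noise_sd <- 0.01                                      # axes ~horizontal
  burst_x <- burst_y <- numeric(length(t))
  if (cfg$target_accel_peak > 0) {
    f <- 8; tau <- 0.15
    on <- t >= cfg$event_time
    ph <- 2 * pi * f * (t[on] - cfg$event_time)
    dec <- exp(-(t[on] - cfg$event_time) / tau)
    burst_x[on] <- cfg$target_accel_peak * sin(ph) * dec
    burst_y[on] <- 0.6 * cfg$target_accel_peak * sin(ph + pi / 2) * dec
  }
  a <- cbind(ax = g[1] + burst_x + rnorm(length(t), sd = noise_sd),
             ay = g[2] + burst_y + rnorm(length(t), sd = noise_sd))
  sensor_stream(a, cfg$fs_accel, axes = 2L)
}

#' Simulate a complete trial bundle
#'
#' Renders a full synthetic trial: clicks at the control-law emission times
#' plus target echoes delayed by the two-way travel time 2 r/c and scaled
#' by two-way spherical spreading (40 log10 r) into band-limited Gaussian
#' noise; a tri-axial body accelerometer with a damped-sinusoid jerk
#' transient starting `response_latency_jerk` after the event; a two-axis
#' target accelerometer with constant gravity offsets and an acceleration
#' burst at the event; and the full ground truth. Identical configs
#' (including `seed`) give identical bundles.
#'
#' @param config a [sim_config()].
#' @param render_audio if `FALSE`, skip audio synthesis (the returned
#'   bundle carries a 1-sample placeholder audio stream); useful for large
#'   click-train-only cohorts.
#' @param trial_id identifier for the bundle.
#' @return A [trial_bundle()] with `ground_truth` populated.
#' @export
simulate_trial <- function(config, render_audio = TRUE, trial_id = "sim") {
  cfg <- config
  sp <- species_preset(cfg$species_preset)
  validate_sim_config(cfg, sp)
  ct <- simulate_click_train(cfg)       # seeds the RNG from cfg$seed
  audio <- if (render_audio) {
    render_audio(cfg, sp, ct$times)
  } else {
    audio_stream(0, cfg$fs_audio)
  }
  body <- render_body_motion(cfg)
  target <- render_target_motion(cfg)
  bundle <- trial_bundle(audio = audio, body_motion = body,
                         target_motion = target,
                         species_preset = cfg$species_preset,
                         event_time = if (render_audio) cfg$event_time else NULL,
                         ground_truth = ct$truth, trial_id = trial_id)
  if (!render_audio) bundle$event_time <- cfg$event_time
  bundle
}

#' Simulate a control (null) trial
#'
#' As [simulate_trial()], but with no target escape and no responses: the
#' range follows the constant closing speed throughout, the ICI follows the
#' same control law (hence stays smooth apart from jitter), and no jerk
#' transient or target burst is rendered. `event_time` is recorded in the
#' bundle but is causally inert, which is exactly what the bootstrap null
#' calibration requires.
#'
#' @inheritParams simulate_trial
#' @return A [trial_bundle()].
#' @export
simulate_null_trial <- function(config, render_audio = TRUE, trial_id = "null") {
  cfg <- config
  cfg$escape_speed_excess <- 0
  cfg$jerk_peak <- 0
  cfg$target_accel_peak <- 0
  cfg$saccade_enabled <- FALSE
  simulate_trial(cfg, render_audio = render_audio, trial_id = trial_id)
}

#' Cue-dependent response latency model
#'
#' In the captive trials, stronger target movement cues elicited faster
#' threshold-crossing responses, with the inverse latency approximately
#' linear in the RMS target acceleration. This helper maps a cue magnitude
#' to a response latency under that model, `latency = 1 / (a + b x cue)`,
#' for building cohorts with a known latency-cue relationship.
#'
#' @param cue RMS target acceleration, m/s^2.
#' @param a intercept of the inverse-latency relation, 1/s.
#' @param b slope, 1/s per m/s^2.
#' @return latency in seconds.
#' @export
latency_from_cue <- function(cue, a = 4, b = 1.5) {
  1 / (a + b * cue)
}
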