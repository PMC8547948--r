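# End-to-end convenience wrappers over the module functions.

#' Run the acoustic pipeline on a trial bundle
#'
#' Detects clicks, forms the echogram and extracts the echo trace, reusing
#' a single band-limited envelope computation across the stages.
#'
#' @param bundle a [trial_bundle()].
#' @param max_range echogram extent, m.
#' @param gate_width,min_snr passed to [extract_trace()].
#' @param sound_speed m/s.
#' @param ... further arguments to [detect_clicks()].
#' @return A list: `train` ([click_train()]), `echogram`, `trace`,
#'   `dof_t`/`dof_m` (the depth-of-field series at the clicks).
#' @export
process_trial <- function(bundle, max_range = 4, gate_width = 0.5,
                          min_snr = 12, sound_speed = 1500, ...) {
  sp <- species_preset(bundle$species_preset)
  env <- band_envelope(bundle$audio, sp$band)
  train <- detect_clicks(bundle$audio, preset = sp$name, env = env, ...)
  if (length(train$times) < 3L)
    stop("insufficient-data error: fewer than 3 clicks detected")
  eg <- form_echogram(bundle$audio, train, preset = sp$name,
                      max_range = max_range, sound_speed = sound_speed,
                      env = env)
  trace <- extract_trace(eg, gate_width = gate_width, min_snr = min_snr)
  list(train = train, echogram = eg, trace = trace,
       dof_t = head(train$times, -1),
       dof_m = ici_to_dof(train$ici, sound_speed))
}

#' Estimate the ICI feedback delay of a trial by loop-area minimisation
#'
#' Full pipeline: click detection, echogram, echo-trace extraction, then
#' [loop_area_latency()] between the extracted prey range and the
#' depth-of-field series derived from the detected ICIs.
#'
#' Before fitting, the extracted range series is cleaned with a 3-point
#' running median, which suppresses isolated mis-gated clicks without
#' shifting the trace in time.
#'
#' @param bundle a [trial_bundle()].
#' @param grid_step,max_advance passed to [loop_area_latency()].
#' @param ... passed to [process_trial()].
#' @return A `latency_estimate` (method `"loop_area"`).
#' @export
estimate_loop_latency <- function(bundle, grid_step = 0.005,
                                  max_advance = 0.3, ...) {
  pr <- process_trial(bundle, ...)
  tr <- pr$trace[pr$trace$valid, ]
  r <- if (nrow(tr) >= 3L) stats::runmed(tr$range, 3) else tr$range
  loop_area_latency(tr$click_time, r, pr$dof_t, pr$dof_m,
                    grid_step = grid_step, max_advance = max_advance)
}

#' Simulate a cohort of trials as (train, event) pairs
#'
#' Generates `n` trials sharing a base configuration, with per-trial
#' variation in the event time (uniform over `event_range`) and
#' independent seeds derived from `seed`, returning the light-weight
#' `(train, event)` form consumed by [bootstrap_null()]. With
#' `null = TRUE` the trials are control trials (no escape, no response)
#' whose recorded event times are causally inert.
#'
#' @param n number of trials.
#' @param config base [sim_config()].
#' @param null generate control trials?
#' @param event_range length-2 range (s) for the per-trial event time.
#' @param seed integer seed for the cohort.
#' @return A list of `n` lists, each with `train`, `event`, `truth`.
#' @export
simulate_stat_cohort <- function(n, config, null = FALSE,
                                 event_range = c(0.9, 1.6), seed = 1L) {
  set.seed(seed)
  events <- runif(n, event_range[1], event_range[2])
  seeds <- sample.int(.Machine$integer.max %/% 2L, n)
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$event_time <- events[i]
    cfg$seed <- seeds[i]
    if (null) {
      cfg$escape_speed_excess <- 0
      cfg$saccade_enabled <- FALSE
    }
    ct <- simulate_click_train(cfg)
    list(train = click_train(ct$times), event = events[i], truth = ct$truth)
  })
}
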