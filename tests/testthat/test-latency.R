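# Threshold-crossing latencies, loop-area minimisation, target cue,
# inverse-latency regression.

test_that("ICI threshold latency finds the first post-event crossing", {
  # ICI steps from 2 ms to 6 ms at event + 0.08 s
  t_fast <- seq(0, 1.08, by = 0.002)
  t_slow <- seq(1.086, 1.5, by = 0.006)
  tr <- click_train(c(t_fast, t_slow))
  est <- threshold_latency_ici(tr, event = 1.0)
  expect_equal(est$value, 0.08, tolerance = 1e-9)
  expect_equal(est$method, "ici_threshold")

  # ICI never exceeds 5 ms: no crossing
  expect_null(threshold_latency_ici(click_train(seq(0, 2, by = 0.004)), 1.0))

  # ICI above threshold before and after the event: first post-event click
  tr3 <- click_train(seq(0, 2, by = 0.008))
  est3 <- threshold_latency_ici(tr3, event = 1.001)
  expect_equal(est3$value, 1.008 - 1.001, tolerance = 1e-9)

  expect_error(threshold_latency_ici(tr3, event = 5), "domain")
})

test_that("jerk threshold latency matches the simulated response delay", {
  cfg <- cohort_cfg(seed = 41, response_latency_jerk = 0.1)
  b <- simulate_trial(cfg, render_audio = FALSE)
  est <- threshold_latency_jerk(b$body_motion, event = cfg$event_time)
  expect_lt(abs(est$value - 0.10), 0.01)
  # quiescent motion: no crossing
  nb <- simulate_null_trial(cfg, render_audio = FALSE)
  expect_null(threshold_latency_jerk(nb$body_motion, event = cfg$event_time))
  # a weak burst (peak 200 m/s^3) stays below the 300 m/s^3 threshold
  cfg2 <- cohort_cfg(seed = 42, jerk_peak = 200)
  b2 <- simulate_trial(cfg2, render_audio = FALSE)
  expect_null(threshold_latency_jerk(b2$body_motion, event = cfg2$event_time))
})

test_that("loop-area minimisation recovers a known pure delay", {
  tt <- seq(0, 4, by = 0.005)
  r <- 2 + 0.5 * sin(2 * pi * 0.8 * tt)
  g <- function(x) 1.4 * x
  for (delay in c(0, 0.09)) {
    dof <- g(2 + 0.5 * sin(2 * pi * 0.8 * (tt - delay)))
    est <- loop_area_latency(tt, r, tt, dof)
    expect_equal(est$value, delay)
  }
  # an off-grid delay quantises to a neighbouring grid point
  dof <- g(2 + 0.5 * sin(2 * pi * 0.8 * (tt - 0.092)))
  est <- loop_area_latency(tt, r, tt, dof)
  expect_true(est$value %in% c(0.090, 0.095))
  # the area at the true advance is below the area at zero advance
  d <- est$detail
  expect_lt(d$area[d$advance == 0.090], d$area[d$advance == 0])
})

test_that("loop-area estimation is invariant to a common time shift", {
  tt <- seq(0, 4, by = 0.005)
  r <- 2 + 0.4 * sin(2 * pi * 0.6 * tt) + 0.1 * sin(2 * pi * 1.7 * tt)
  doff <- stats::approxfun(tt, 1.4 * r, rule = 2)
  dof <- doff(tt - 0.06)
  e1 <- loop_area_latency(tt, r, tt, dof)
  e2 <- loop_area_latency(tt + 100, r, tt + 100, dof)
  expect_equal(e1$value, e2$value)
  expect_equal(e1$value, 0.06)
})

test_that("degenerate inputs to the loop estimator are rejected", {
  tt <- seq(0, 2, by = 0.01)
  expect_error(loop_area_latency(tt, rep(2, length(tt)), tt, 1.4 * tt),
               "degenerate")
  expect_error(loop_area_latency(tt[1:20], 2 + sin(tt[1:20]), tt[1:20],
                                 rep(1, 20), max_advance = 0.3),
               "common support")
})

test_that("the RMS target-acceleration cue matches closed forms", {
  fs <- 200
  t <- seq(0, 3, by = 1 / fs)
  g <- c(0.3, -0.2)
  # static stream: gravity offsets only, no transient
  static <- sensor_stream(cbind(g[1], g[2])[rep(1, length(t)), ], fs, axes = 2)
  expect_null(rms_target_acceleration(static))
  # single-axis sinusoid of amplitude A from t = 1.5: rms = A / sqrt(2)
  A <- 4
  burst <- ifelse(t >= 1.5, A * sin(2 * pi * 8 * (t - 1.5)), 0)
  one_axis <- sensor_stream(cbind(g[1] + burst, g[2]), fs, axes = 2)
  cue <- rms_target_acceleration(one_axis)
  expect_equal(cue$onset_time, 1.5, tolerance = 0.02)
  expect_equal(cue$rms_accel, A / sqrt(2), tolerance = 0.02 * A)
  # quadrature sinusoids on both axes: rms = A
  b2 <- ifelse(t >= 1.5, A * cos(2 * pi * 8 * (t - 1.5)), 0)
  two_axis <- sensor_stream(cbind(g[1] + burst, g[2] + b2), fs, axes = 2)
  cue2 <- rms_target_acceleration(two_axis)
  expect_equal(cue2$rms_accel, A, tolerance = 0.02 * A)
})

test_that("inverse-latency regression recovers exact and degenerate fits", {
  x <- c(0.5, 1, 1.5, 2.5, 4)
  tau <- 1 / (2 * x + 1)
  fit <- suppressWarnings(inverse_latency_regression(tau, x))  # exact fit
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$intercept, 1, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant latency: no relation
  fit0 <- inverse_latency_regression(rep(0.1, 5), x)
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$r_squared, 0)
  expect_error(inverse_latency_regression(c(0.1, 0.2), c(1, 2)),
               "insufficient-data")
})

test_that("cue-dependent latencies give positive regression slopes", {
  set.seed(19)
  n_pos <- 0
  for (rep in 1:20) {
    cues <- runif(30, 0.5, 5)
    lat <- latency_from_cue(cues) * exp(rnorm(30, sd = 0.15))
    fit <- inverse_latency_regression(lat, cues)
    n_pos <- n_pos + (fit$slope > 0)
  }
  expect_gte(n_pos, 19)
})
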