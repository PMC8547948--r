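# Event-locked delta-ICI and jerk statistics, bootstrap null, analytic
# helpers.

test_that("monotone click trains give all-zero / all-one bin proportions", {
  # accelerating train: ICI strictly decreasing -> no positive changes
  ici_acc <- seq(0.012, 0.004, length.out = 200)
  tr_acc <- click_train(cumsum(c(0, ici_acc)))
  event <- max(tr_acc$times) / 2
  p <- delta_ici_proportions(tr_acc, event, bin_width = 0.05)
  expect_true(all(p$proportion[p$n > 0] == 0))
  # decelerating train: all changes positive
  tr_dec <- click_train(cumsum(c(0, rev(ici_acc))))
  p2 <- delta_ici_proportions(tr_dec, event, bin_width = 0.05)
  expect_true(all(p2$proportion[p2$n > 0] == 1))
})

test_that("alternating jitter about a constant ICI gives proportions of 0.5", {
  ici <- 0.005 + rep(c(-1e-4, 1e-4), 200)
  tr <- click_train(cumsum(c(0, ici)))
  p <- delta_ici_proportions(tr, event = 1.0, bin_width = 0.05)
  expect_true(all(abs(p$proportion[p$n > 0] - 0.5) <= 1 / pmax(p$n[p$n > 0], 1)))
})

test_that("bin accounting is exact and matches a direct count", {
  set.seed(5)
  ici <- runif(400, 0.003, 0.008)
  tr <- click_train(cumsum(c(0, ici)))
  event <- 1.0
  p <- delta_ici_proportions(tr, event, bin_width = 0.05)
  dici <- diff(tr$ici)
  t_rel <- tr$times[-(1:2)] - event
  for (i in seq_len(nrow(p))) {
    inb <- t_rel >= p$bin_start[i] & t_rel < p$bin_end[i]
    if (i == nrow(p)) inb <- t_rel >= p$bin_start[i] & t_rel <= p$bin_end[i]
    expect_equal(p$n[i], sum(inb))
    expect_equal(p$n_pos[i], sum(dici[inb] > 0))
  }
  # positives + non-positives = total
  expect_true(all(p$n_pos <= p$n))
})

test_that("exchangeable ICI noise gives proportions of 0.5 on average", {
  set.seed(77)
  props <- replicate(30, {
    ici <- 0.005 * exp(rnorm(300, sd = 0.05))
    tr <- click_train(cumsum(c(0, ici)))
    p <- delta_ici_proportions(tr, event = 0.75, bin_width = 0.05)
    mean(p$proportion, na.rm = TRUE)
  })
  n_eff <- 30 * 280   # delta-ICIs contributing over all replicates
  expect_lt(abs(mean(props) - 0.5), 3 * 0.5 / sqrt(n_eff) + 0.01)
})

test_that("norm-jerk behaves like a derivative magnitude", {
  fs <- 200
  t <- seq(0, 2, by = 1 / fs)
  # constant acceleration: zero jerk
  const <- sensor_stream(cbind(1, 2, 9.81)[rep(1, length(t)), ], fs)
  expect_true(all(norm_jerk(const)$jerk == 0))
  jb <- jerk_rms_bins(const, event = 1, bin_width = 0.05)
  expect_true(all(jb$rms_jerk[jb$n > 0] == 0))
  # single-axis ramp of slope s: jerk = s everywhere
  s <- 120
  ramp <- sensor_stream(cbind(s * t, 0, 0), fs)
  expect_equal(unique(round(norm_jerk(ramp)$jerk, 6)), s)
  jb2 <- jerk_rms_bins(ramp, event = 1, bin_width = 0.05)
  expect_true(all(abs(jb2$rms_jerk[jb2$n > 0] - s) < 1e-6))
  # sub-additivity, equality for collinear signals
  set.seed(3)
  a1 <- matrix(rnorm(300), ncol = 3)
  a2 <- matrix(rnorm(300), ncol = 3)
  j1 <- norm_jerk(sensor_stream(a1, fs))$jerk
  j2 <- norm_jerk(sensor_stream(a2, fs))$jerk
  j12 <- norm_jerk(sensor_stream(a1 + a2, fs))$jerk
  expect_true(all(j12 <= j1 + j2 + 1e-9))
  jcol <- norm_jerk(sensor_stream(a1 * 2, fs))$jerk
  expect_equal(jcol, 2 * j1, tolerance = 1e-12)
})

test_that("a simulated jerk burst lands in the bin of its true delay", {
  # a vigorous response: with the burst starting 0.08 s after the event,
  # its bin is only 40% occupied, so the peak must be well above 300 m/s^3
  # for the bin RMS to cross it
  cfg <- cohort_cfg(seed = 31, response_latency_jerk = 0.08, jerk_peak = 800)
  b <- simulate_trial(cfg, render_audio = FALSE)
  jb <- jerk_rms_bins(b$body_motion, event = cfg$event_time, bin_width = 0.05)
  over <- jb$bin_start[!is.na(jb$rms_jerk) & jb$rms_jerk > 300]
  expect_equal(min(over), 0.05)   # first bin over 300 m/s^3 is [0.05, 0.10)
})

test_that("bootstrap input validation", {
  co <- simulate_stat_cohort(3, cohort_cfg(), null = TRUE, seed = 2)
  expect_error(bootstrap_null(co, "dici", n_rep = 0), "n_rep")
  expect_error(bootstrap_null(co[1], "dici"), "2 trials")
})

test_that("transplanting a trial's own offset reproduces its statistic", {
  co <- simulate_stat_cohort(4, cohort_cfg(), null = TRUE, seed = 9)
  for (tr in co) {
    t0 <- tr$train$times[1]
    mock <- t0 + (tr$event - t0)
    expect_identical(delta_ici_proportions(tr$train, mock, 0.05),
                     delta_ici_proportions(tr$train, tr$event, 0.05))
  }
})

test_that("identical trials produce tied replicates and no significance", {
  one <- simulate_stat_cohort(1, cohort_cfg(), null = TRUE, seed = 12)[[1]]
  br <- bootstrap_null(list(one, one, one), "dici", bin_width = 0.05,
                       n_rep = 50, seed = 1)
  # every replicate equals the observed statistic: mid-rank exceedance 0.5
  expect_true(all(abs(br$bins$exceed_frac[is.finite(br$bins$exceed_frac)] - 0.5)
                  < 1e-12))
  expect_false(any(br$bins$significant))
})

test_that("a strong delayed response is detected in the correct bin", {
  cfg <- cohort_cfg(escape_speed_excess = 1.5, response_latency = 0.075,
                    saccade_enabled = TRUE, ici_jitter = 0.01)
  co <- simulate_stat_cohort(20, cfg, null = FALSE, seed = 5)
  br <- bootstrap_null(co, "dici", bin_width = 0.05, n_rep = 200, seed = 3)
  sig <- br$bins$bin_start[br$bins$significant]
  expect_true(length(sig) > 0)
  expect_equal(min(sig), 0.05)
  # pooled aggregate mode reaches the same first significant bin
  br2 <- bootstrap_null(co, "dici", bin_width = 0.05, n_rep = 200, seed = 3,
                        aggregate = "pooled")
  expect_equal(min(br2$bins$bin_start[br2$bins$significant]), 0.05)
})

test_that("depth of field, bandwidth ratio and click counts are exact", {
  expect_equal(ici_to_dof(0.005, 1500), 3.75)
  expect_equal(ici_to_dof(0, 1500), 0)
  x <- c(0.0021, 0.005, 0.08)
  expect_equal(dof_to_ici(ici_to_dof(x)), x)
  expect_error(ici_to_dof(-1), "domain")

  expect_equal(bandwidth_ratio(0.0025, 0.05), 40)
  expect_equal(bandwidth_ratio(0.004, 0.002), 1)
  expect_equal(bandwidth_ratio(0.0035, 0.175), 100)
  expect_error(bandwidth_ratio(0, 0.1), "domain")

  expect_equal(clicks_per_latency(0.05, 0.0025), 20)
  expect_equal(clicks_per_latency(0, 0.0025), 0)
  expect_equal(clicks_per_latency(0.2, 0.0035), 57)
  expect_error(clicks_per_latency(0.1, 0), "domain")
})
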