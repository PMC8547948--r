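# Sensor-motor latency estimation: threshold crossings on ICI and RMS jerk,
# loop-area minimisation between prey range and depth of field, the RMS
# target-acceleration cue, and the inverse-latency regression.

latency_estimate <- function(method, value, threshold = NA_real_,
                             grid_step = NA_real_, detail = NULL) {
  structure(list(method = method, value = value, threshold = threshold,
                 grid_step = grid_step, detail = detail),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> %s: %.3f s", x$method, x$value))
  if (is.finite(x$threshold)) cat(sprintf(" (threshold %g)", x$threshold))
  cat("\n")
  invisible(x)
}

#' ICI threshold-crossing latency
#'
#' The delay from the event to the first post-event click whose forward
#' ICI exceeds `thresh` (default 5 ms, i.e. a depth of field beyond
#' 3.75 m) -- the onset of a strong outward biosonar adjustment. Crossings
#' before the event are ignored.
#'
#' @param train a [click_train()].
#' @param event event time, s (must lie within the train's span).
#' @param thresh ICI threshold, s.
#' @return A `latency_estimate` (method `"ici_threshold"`), or `NULL` if
#'   the ICI never exceeds the threshold after the event.
#' @export
threshold_latency_ici <- function(train, event, thresh = 0.005) {
  if (length(train$times) < 2L)
    stop("insufficient-data error: need at least 2 clicks")
  if (event < min(train$times) || event > max(train$times))
    stop("domain error: event outside the click-train record")
  post <- which(train$times >= event)
  post <- post[post <= length(train$ici)]   # clicks with a forward ICI
  if (!length(post)) return(NULL)
  hit <- post[train$ici[post] > thresh]
  if (!length(hit)) return(NULL)
  latency_estimate("ici_threshold", train$times[hit[1]] - event,
                   threshold = thresh)
}

#' Jerk threshold-crossing latency
#'
#' The delay from the event to the first post-event time at which the RMS
#' norm-jerk (root mean square over a sliding window, default 10 ms)
#' exceeds `thresh` (default 300 m/s^3) -- the onset of a strong kinematic
#' response.
#'
#' @param motion a tri-axial [sensor_stream()].
#' @param event event time, s (within the record).
#' @param thresh RMS jerk threshold, m/s^3.
#' @param rms_window sliding RMS window length, s.
#' @return A `latency_estimate` (method `"jerk_threshold"`), or `NULL` if
#'   there is no crossing.
#' @export
threshold_latency_jerk <- function(motion, event, thresh = 300,
                                   rms_window = 0.010) {
  nj <- norm_jerk(motion)
  if (event < 0 || event > max(nj$t))
    stop("domain error: event outside the motion record")
  w <- max(1L, round(rms_window * motion$fs))
  rms <- sqrt(stats::filter(nj$jerk^2, rep(1 / w, w), sides = 2))
  hit <- which(nj$t >= event & is.finite(rms) & rms > thresh)
  if (!length(hit)) return(NULL)
  latency_estimate("jerk_threshold", nj$t[hit[1]] - event, threshold = thresh)
}

# absolute shoelace area of the polygon traced by (x, y), closed from the
# last point back to the first
shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  xn <- c(x, x[1]); yn <- c(y, y[1])
  abs(sum(x * yn[-1] - xn[-1] * y)) / 2
}

#' Loop-area latency between prey range and depth of field
#'
#' When the ICI response lags prey movement, a plot of prey range against
#' the acoustic depth of field traces anticlockwise hysteresis loops.
#' Advancing the depth-of-field series in steps until the enclosed loop
#' area is minimised estimates the feedback delay. Both series are
#' linearly interpolated onto a common uniform time base (default 200 Hz);
#' for each candidate advance `a` in `{0, grid_step, ..., max_advance}`
#' the depth-of-field series is shifted earlier by `a` and the absolute
#' shoelace area of the closed (range, dof) polygon over the overlap is
#' computed. The advance minimising the area is returned; ties go to the
#' smallest advance.
#'
#' @param range_t,range_m times (s) and prey ranges (m) of the echo trace.
#' @param dof_t,dof_m times (s) and depth-of-field values (m), e.g.
#'   `ici_to_dof()` of the forward ICI at each click.
#' @param grid_step advance step, s (default 0.005).
#' @param max_advance largest advance tried, s (default 0.3).
#' @param interp_fs common interpolation rate, Hz.
#' @return A `latency_estimate` (method `"loop_area"`) whose `detail` holds
#'   the tested advances and their areas.
#' @export
loop_area_latency <- function(range_t, range_m, dof_t, dof_m,
                              grid_step = 0.005, max_advance = 0.3,
                              interp_fs = 200) {
  ok_r <- is.finite(range_t) & is.finite(range_m)
  ok_d <- is.finite(dof_t) & is.finite(dof_m)
  range_t <- range_t[ok_r]; range_m <- range_m[ok_r]
  dof_t <- dof_t[ok_d]; dof_m <- dof_m[ok_d]
  if (length(range_m) < 3L || var(range_m) == 0)
    stop("estimation error: degenerate (constant or empty) range series")
  t0 <- max(min(range_t), min(dof_t))
  t1 <- min(max(range_t), max(dof_t))
  if (t1 - t0 < 2 * max_advance)
    stop("estimation error: common support shorter than 2x max_advance")
  rf <- approxfun(range_t, range_m)
  df <- approxfun(dof_t, dof_m)
  advances <- seq(0, max_advance, by = grid_step)
  # every advance is scored over the same evaluation window so that the
  # area comparison is not confounded by the length of the overlap
  tt <- seq(t0, t1 - max_advance, by = 1 / interp_fs)
  areas <- vapply(advances, function(a) {
    shoelace_area(rf(tt), df(tt + a))
  }, numeric(1))
  best <- which.min(areas)    # which.min takes the first (smallest) on ties
  latency_estimate("loop_area", advances[best], grid_step = grid_step,
                   detail = data.frame(advance = advances, area = areas))
}

#' RMS target acceleration cue
#'
#' Quantifies the strength of a target-movement cue from the target's
#' two-axis accelerometer: the fixed gravity component is removed as the
#' per-axis mean over a pre-onset baseline, the onset is the first time
#' either demeaned axis exceeds `onset_factor` baseline standard
#' deviations, and the cue is the root mean square of the summed squared
#' axes over the `window` (0.5 s) following the onset.
#'
#' @param target_motion a two-axis [sensor_stream()].
#' @param window RMS window after onset, s.
#' @param baseline_dur baseline span used for the gravity estimate, s.
#' @param onset_factor onset threshold in baseline standard deviations.
#' @return A list of class `target_cue` with `rms_accel` (m/s^2),
#'   `onset_time` (s), `window` (s), or `NULL` if no transient is found
#'   (the "no-cue" signal).
#' @export
rms_target_acceleration <- function(target_motion, window = 0.5,
                                    baseline_dur = 1.0, onset_factor = 5) {
  a <- target_motion$accel
  fs <- target_motion$fs
  t <- stream_times(target_motion)
  nb <- max(2L, min(nrow(a), round(baseline_dur * fs)))
  g <- colMeans(a[seq_len(nb), , drop = FALSE])
  s <- pmax(apply(a[seq_len(nb), , drop = FALSE], 2, sd), 1e-12)
  d <- sweep(a, 2, g)
  over <- abs(d[, 1]) > onset_factor * s[1] | abs(d[, 2]) > onset_factor * s[2]
  if (!any(over)) return(NULL)
  i0 <- which(over)[1]
  if (t[i0] + window > max(t) + 1 / fs)
    stop("insufficient-data error: stream must extend ", window,
         " s beyond the onset")
  win <- which(t >= t[i0] & t < t[i0] + window)
  rms <- sqrt(mean(d[win, 1]^2 + d[win, 2]^2))
  structure(list(rms_accel = rms, onset_time = t[i0], window = window),
            class = "target_cue")
}

#' Inverse-latency regression on cue magnitude
#'
#' Ordinary least squares of `1/latency` on the RMS target-acceleration
#' cue; the reciprocal linearises the latency-cue relationship. Returns
#' the slope, intercept, coefficient of determination and the two-sided
#' p-value of the slope. With constant latencies (zero variance in
#' `1/latency`) the slope and r-squared are 0 and the p-value 1.
#'
#' @param latencies response latencies, s (> 0).
#' @param cues RMS target accelerations, m/s^2.
#' @return A list: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
inverse_latency_regression <- function(latencies, cues) {
  ok <- is.finite(latencies) & is.finite(cues)
  latencies <- latencies[ok]; cues <- cues[ok]
  if (length(latencies) < 3L)
    stop("insufficient-data error: need at least 3 paired observations")
  if (any(latencies <= 0)) stop("domain error: latencies must be > 0")
  y <- 1 / latencies
  if (var(y) == 0) {
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                p_value = 1, n = length(y)))
  }
  fit <- lm(y ~ cues)
  sm <- summary(fit)
  p <- if (nrow(sm$coefficients) >= 2L) sm$coefficients[2, 4] else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared, p_value = p, n = length(y))
}
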