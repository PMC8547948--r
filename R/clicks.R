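# Click detection, ICI computation and buzz segmentation.

#' Band-limited Hilbert envelope of an audio stream
#'
#' Bandpass filters the audio with a zero-phase Butterworth design at the
#' given band edges (applied forwards and backwards so click/echo timing is
#' unbiased) and returns the amplitude envelope, i.e. the magnitude of the
#' analytic signal computed via the FFT.
#'
#' @param audio an [audio_stream()].
#' @param band numeric length-2, band edges in Hz; must lie inside Nyquist.
#' @param order Butterworth prototype order (default 4).
#' @return numeric vector, same length as the audio, envelope amplitude.
#' @export
band_envelope <- function(audio, band, order = 4) {
  fs <- audio$fs
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2])
    stop("parameter error: band must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, audio$samples)
  n <- length(x)
  nfft <- nextn(n, c(2, 3, 5))
  X <- fft(c(x, numeric(nfft - n)))
  h <- numeric(nfft)
  if (nfft %% 2 == 0) {
    h[1] <- 1; h[nfft / 2 + 1] <- 1; h[2:(nfft / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nfft + 1) / 2)] <- 2
  }
  analytic <- fft(X * h, inverse = TRUE) / nfft
  Mod(analytic[seq_len(n)])
}

#' Construct a click train
#'
#' @param times strictly increasing click emission times, s.
#' @return An object of class `click_train` with fields `times` and `ici`
#'   (forward inter-click intervals, `ici[k] = times[k+1] - times[k]`).
#' @export
click_train <- function(times) {
  times <- as.numeric(times)
  if (length(times) >= 2L && any(diff(times) <= 0))
    stop("click_train invariant violated: times strictly increasing")
  structure(list(times = times, ici = if (length(times) >= 2L) diff(times)
                                      else numeric(0)),
            class = "click_train")
}

#' @export
print.click_train <- function(x, ...) {
  cat(sprintf("<click_train> %d clicks", length(x$times)))
  if (length(x$ici)) cat(sprintf(", ICI %.2f-%.2f ms (median %.2f)",
                                 1000 * min(x$ici), 1000 * max(x$ici),
                                 1000 * median(x$ici)))
  cat("\n")
  invisible(x)
}

#' Detect echolocation clicks in tag audio
#'
#' An automated energy detector standing in for supervised click audits:
#' the band-limited Hilbert envelope is compared against a running noise
#' floor (median envelope over 50 ms blocks, scaled by `1/sqrt(ln 2)` to
#' the RMS-equivalent level for a Rayleigh envelope). Local envelope maxima
#' exceeding the floor by `thresh_db` are candidate clicks; candidates are
#' accepted in decreasing amplitude order subject to a blanking interval,
#' and finally a relative-amplitude gate rejects detections more than
#' `rel_thresh_db` below the 90th percentile of accepted peak heights --
#' on-animal clicks are far stronger than any returning echo, so this
#' separates the outgoing clicks from strong target echoes at close range.
#'
#' @param audio an [audio_stream()].
#' @param preset `"pp"` or `"md"`; supplies the analysis band and default
#'   blanking (half the minimum expected buzz ICI).
#' @param band override the analysis band, Hz.
#' @param thresh_db detection threshold above the noise floor, dB.
#' @param blanking minimum separation between detections, s.
#' @param rel_thresh_db relative gate below the 90th-percentile peak, dB;
#'   `Inf` disables the gate.
#' @param env optionally, a precomputed [band_envelope()] for this audio,
#'   to avoid refiltering.
#' @return A [click_train()] (possibly empty).
#' @export
detect_clicks <- function(audio, preset = "pp", band = NULL,
                          thresh_db = 15, blanking = NULL,
                          rel_thresh_db = 12, env = NULL) {
  sp <- species_preset(preset)
  if (is.null(band)) band <- sp$band
  if (is.null(blanking)) blanking <- sp$ici_min / 2
  if (blanking <= 0) stop("parameter error: blanking must be > 0")
  fs <- audio$fs
  if (is.null(env)) env <- band_envelope(audio, band)
  n <- length(env)

  # running noise floor: median over 50 ms blocks, interpolated
  blk <- max(16L, round(0.05 * fs))
  nb <- max(1L, n %/% blk)
  idx_end <- pmin(seq_len(nb) * blk, n)
  idx_start <- idx_end - blk + 1L
  med <- vapply(seq_len(nb),
                function(i) median(env[idx_start[i]:idx_end[i]]), numeric(1))
  centres <- (idx_start + idx_end) / 2
  floor_rms <- if (nb > 1L) {
    approx(centres, med, xout = seq_len(n), rule = 2)$y / sqrt(log(2))
  } else rep(med / sqrt(log(2)), n)
  # guard against a degenerate (noiseless) floor
  floor_rms <- pmax(floor_rms, max(env) * 1e-6)

  thr <- floor_rms * 10^(thresh_db / 20)
  above <- which(env > thr)
  if (!length(above)) return(click_train(numeric(0)))

  # peak per contiguous run above threshold
  run_starts <- c(1L, which(diff(above) > 1L) + 1L)
  run_ends <- c(run_starts[-1L] - 1L, length(above))
  peaks <- vapply(seq_along(run_starts), function(i) {
    seg <- above[run_starts[i]:run_ends[i]]
    seg[which.max(env[seg])]
  }, integer(1))

  # amplitude-ordered greedy blanking
  blank_n <- round(blanking * fs)
  ord <- order(env[peaks], decreasing = TRUE)
  keep <- logical(length(peaks))
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(peaks[i] - taken) >= blank_n)) {
      keep[i] <- TRUE
      taken <- c(taken, peaks[i])
    }
  }
  peaks <- sort(peaks[keep])
  if (is.finite(rel_thresh_db) && length(peaks) > 1L) {
    gate <- quantile(env[peaks], 0.9, names = FALSE) * 10^(-rel_thresh_db / 20)
    peaks <- peaks[env[peaks] >= gate]
  }
  click_train((peaks - 1) / fs)
}

#' Forward inter-click intervals of a click train
#'
#' @param train a [click_train()] or a numeric vector of click times.
#' @return numeric vector of forward differences (length n-1).
#' @export
compute_ici <- function(train) {
  times <- if (inherits(train, "click_train")) train$times else as.numeric(train)
  if (length(times) < 2L)
    stop("insufficient-data error: need at least 2 clicks to compute ICI")
  diff(times)
}

#' Segment buzzes from a click train
#'
#' A buzz is a maximal run of consecutive ICIs below the species threshold
#' (13 ms for `"pp"`, 100 ms for `"md"`) whose time span -- first to last
#' click of the run -- is at least `min_duration` (0.5 s).
#'
#' @param train a [click_train()].
#' @param preset `"pp"` or `"md"`.
#' @param threshold override the ICI threshold, s.
#' @param min_duration minimum buzz duration, s.
#' @return A data.frame with one row per buzz: `start_index`, `end_index`
#'   (click indices, inclusive), `start_time`, `end_time`, `duration`,
#'   `threshold_used`, `n_clicks`. Zero rows if no buzz qualifies.
#' @export
segment_buzzes <- function(train, preset = "pp", threshold = NULL,
                           min_duration = NULL) {
  sp <- species_preset(preset)
  if (is.null(threshold)) threshold <- sp$buzz_ici_max
  if (is.null(min_duration)) min_duration <- sp$buzz_min_duration
  empty <- data.frame(start_index = integer(0), end_index = integer(0),
                      start_time = numeric(0), end_time = numeric(0),
                      duration = numeric(0), threshold_used = numeric(0),
                      n_clicks = integer(0))
  if (length(train$ici) < 1L) return(empty)
  below <- train$ici < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- lapply(which(r$values), function(j) {
    i0 <- starts[j]                 # first ICI index of the run
    i1 <- ends[j]                   # last ICI index -> clicks i0 .. i1+1
    dur <- train$times[i1 + 1L] - train$times[i0]
    if (dur < min_duration) return(NULL)
    data.frame(start_index = i0, end_index = i1 + 1L,
               start_time = train$times[i0], end_time = train$times[i1 + 1L],
               duration = dur, threshold_used = threshold,
               n_clicks = i1 + 2L - i0)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
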