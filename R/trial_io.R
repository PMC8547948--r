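# Trial bundle I/O: WAV audio, CSV motion streams, JSON metadata, bundled in
# a plain directory (one directory per trial). All times are seconds relative
# to record start; time zero is the first audio sample.

#' Construct an audio stream
#'
#' @param samples numeric vector of pressure samples, dimensionless PCM in
#'   `[-1, 1]` (or micro-Pascal referenced if `clip_level` is given).
#' @param fs sampling rate in Hz.
#' @param clip_level optional clipping level, dB re 1 uPa.
#' @return An object of class `audio_stream`.
#' @export
audio_stream <- function(samples, fs, clip_level = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio_stream invariant violated: length >= 1")
  if (!all(is.finite(samples))) stop("audio_stream invariant violated: samples finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("audio_stream invariant violated: fs > 0")
  structure(list(samples = samples, fs = fs, clip_level = clip_level),
            class = "audio_stream")
}

#' @export
print.audio_stream <- function(x, ...) {
  cat(sprintf("<audio_stream> %d samples @ %g kHz (%.3f s)\n",
              length(x$samples), x$fs / 1000, length(x$samples) / x$fs))
  invisible(x)
}

#' Construct a sensor (accelerometer) stream
#'
#' @param accel numeric matrix of accelerations in m/s^2, one column per
#'   axis. Tag body motion is tri-axial (3 columns); the target
#'   accelerometer is two-axis (2 columns).
#' @param fs sampling rate in Hz.
#' @param axes expected number of axes (columns); default 3.
#' @return An object of class `sensor_stream`.
#' @export
sensor_stream <- function(accel, fs, axes = 3L) {
  accel <- as.matrix(accel)
  if (ncol(accel) != axes)
    stop(sprintf("sensor_stream invariant violated: expected %d channels, got %d",
                 axes, ncol(accel)))
  if (!all(is.finite(accel))) stop("sensor_stream invariant violated: accel finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sensor_stream invariant violated: fs > 0")
  structure(list(accel = accel, fs = fs), class = "sensor_stream")
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(sprintf("<sensor_stream> %d x %d @ %g Hz (%.2f s)\n",
              nrow(x$accel), ncol(x$accel), x$fs, nrow(x$accel) / x$fs))
  invisible(x)
}

#' Sample times of a sensor stream
#'
#' Sample k is at time (k-1)/fs, with time zero shared with the audio.
#' @param stream a `sensor_stream`.
#' @return numeric vector of sample times in seconds.
#' @export
stream_times <- function(stream) {
  (seq_len(nrow(stream$accel)) - 1) / stream$fs
}

#' Construct and validate a trial bundle
#'
#' A trial bundle collects the per-trial data analysed by the pipeline:
#' hydrophone audio, the tag's tri-axial body accelerometer, optionally the
#' two-axis target accelerometer, trial metadata, and (for synthetic trials)
#' the ground truth. All streams share time zero = first audio sample.
#'
#' @param audio an [audio_stream()].
#' @param body_motion a tri-axial [sensor_stream()], or `NULL`.
#' @param target_motion a two-axis [sensor_stream()], or `NULL`.
#' @param species_preset `"pp"` or `"md"`.
#' @param event_time time of the prey/target movement in seconds, or `NULL`
#'   if unknown.
#' @param ground_truth a list as produced by [simulate_trial()], or `NULL`.
#' @param trial_id identifier string.
#' @return An object of class `trial_bundle`.
#' @export
trial_bundle <- function(audio, body_motion = NULL, target_motion = NULL,
                         species_preset = "pp", event_time = NULL,
                         ground_truth = NULL, trial_id = "trial") {
  if (!inherits(audio, "audio_stream"))
    stop("trial_bundle invariant violated: audio must be an audio_stream")
  if (!is.null(body_motion) && !inherits(body_motion, "sensor_stream"))
    stop("trial_bundle invariant violated: body_motion must be a sensor_stream")
  if (!is.null(target_motion) && !inherits(target_motion, "sensor_stream"))
    stop("trial_bundle invariant violated: target_motion must be a sensor_stream")
  species_preset <- species_preset(species_preset)$name
  duration <- length(audio$samples) / audio$fs
  if (!is.null(event_time)) {
    if (!is.finite(event_time) || event_time < 0 || event_time > duration)
      stop("trial_bundle invariant violated: event_time within record duration")
  }
  structure(list(audio = audio, body_motion = body_motion,
                 target_motion = target_motion,
                 species_preset = species_preset,
                 event_time = event_time, ground_truth = ground_truth,
                 trial_id = as.character(trial_id)),
            class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf("<trial_bundle> %s [%s] %.2f s audio @ %g kHz", x$trial_id,
              x$species_preset, length(x$audio$samples) / x$audio$fs,
              x$audio$fs / 1000))
  if (!is.null(x$body_motion)) cat(sprintf(", accel @ %g Hz", x$body_motion$fs))
  if (!is.null(x$target_motion)) cat(", target accel")
  if (!is.null(x$event_time)) cat(sprintf(", event @ %.3f s", x$event_time))
  if (!is.null(x$ground_truth)) cat(", ground truth")
  cat("\n")
  invisible(x)
}

# ---- WAV (16-bit PCM RIFF/WAVE) ------------------------------------------

#' Write a mono 16-bit PCM WAV file
#'
#' Samples in `[-1, 1)` are scaled by 32768 and rounded (the same scale the
#' reader uses, so write/read round-trips are idempotent); values outside
#' the representable range are clipped to full scale.
#'
#' @param samples numeric vector in `[-1, 1]`.
#' @param fs sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, fs, path) {
  pcm <- as.integer(pmax(-32768, pmin(32767, round(samples * 32768))))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 2L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")          # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")  # byte rate
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2L * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a PCM WAV file as an audio stream
#'
#' Reads 16-bit PCM RIFF/WAVE. Samples are scaled to `[-1, 1)` by 1/32768
#' (a full-scale 16-bit sample reads as 1.0 to within one LSB). Stereo
#' files are accepted but only channel 0 is kept, with a message; the
#' pipeline is mono.
#'
#' @param path file path.
#' @param clip_level optional clipping level (dB re 1 uPa) recorded on the
#'   returned stream.
#' @return An [audio_stream()].
#' @export
read_audio <- function(path, clip_level = NULL) {
  if (!file.exists(path)) stop("format error: file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("format error: not a RIFF/WAVE file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("format error: not a RIFF/WAVE file: ", path)
  fs <- NULL; n_chan <- NULL; bits <- NULL; fmt_code <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L)
      stop("format error: no data chunk found in ", path)
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, "integer", 1, size = 2, endian = "little")
      n_chan <- readBin(con, "integer", 1, size = 2, endian = "little")
      fs <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "integer", 1, size = 2, endian = "little")
      bits <- readBin(con, "integer", 1, size = 2, endian = "little")
      if (sz > 16L) readBin(con, "raw", sz - 16L)
    } else if (identical(id, "data")) {
      if (is.null(fmt_code)) stop("format error: data chunk before fmt in ", path)
      if (fmt_code != 1L || bits != 16L)
        stop("format error: only 16-bit PCM WAV is supported (", path, ")")
      pcm <- readBin(con, "integer", n = sz %/% 2L, size = 2, endian = "little")
      if (n_chan > 1L) {
        message("read_audio: ", n_chan, "-channel file; keeping channel 0 only")
        pcm <- pcm[seq(1L, length(pcm), by = n_chan)]
      }
      return(audio_stream(pcm / 32768, fs, clip_level = clip_level))
    } else {
      readBin(con, "raw", sz + (sz %% 2L))  # skip unknown chunk (padded)
    }
  }
}

# ---- bundle directory format ---------------------------------------------

motion_to_df <- function(stream, axes) {
  df <- data.frame(t = stream_times(stream))
  for (i in seq_along(axes)) df[[axes[i]]] <- stream$accel[, i]
  df
}

df_to_motion <- function(df, axes, what) {
  missing_cols <- setdiff(c("t", axes), names(df))
  if (length(missing_cols))
    stop("schema error: ", what, " is missing variable(s): ",
         paste(missing_cols, collapse = ", "))
  dt <- diff(df$t)
  fs <- 1 / median(dt)
  sensor_stream(as.matrix(df[axes]), fs, axes = length(axes))
}

#' Write a trial bundle to disk
#'
#' The bundle is stored as a directory: `audio.wav` (16-bit PCM),
#' `body_motion.csv` and `target_motion.csv` (columns `t,ax,ay,az` /
#' `t,ax,ay`), and `metadata.json` holding the trial id, species preset,
#' sampling rates, event time and, for synthetic trials, the full ground
#' truth. The bundle is validated before anything is written.
#'
#' @param bundle a [trial_bundle()].
#' @param path directory to create (or overwrite the contents of).
#' @return `path`, invisibly.
#' @export
write_trial_bundle <- function(bundle, path) {
  if (!inherits(bundle, "trial_bundle"))
    stop("validation error: not a trial_bundle")
  # re-validate (the constructor enforces invariants; guard mutated objects)
  trial_bundle(bundle$audio, bundle$body_motion, bundle$target_motion,
               bundle$species_preset, bundle$event_time, bundle$ground_truth,
               bundle$trial_id)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_wav(bundle$audio$samples, bundle$audio$fs, file.path(path, "audio.wav"))
  meta <- list(
    schema = "echokin-trial-bundle-v1",
    trial_id = bundle$trial_id,
    species_preset = bundle$species_preset,
    fs_audio = bundle$audio$fs,
    clip_level = bundle$audio$clip_level,
    event_time = bundle$event_time,
    ground_truth = bundle$ground_truth
  )
  if (!is.null(bundle$body_motion)) {
    write.csv(motion_to_df(bundle$body_motion, c("ax", "ay", "az")),
              file.path(path, "body_motion.csv"), row.names = FALSE)
    meta$fs_accel <- bundle$body_motion$fs
  }
  if (!is.null(bundle$target_motion)) {
    write.csv(motion_to_df(bundle$target_motion, c("ax", "ay")),
              file.path(path, "target_motion.csv"), row.names = FALSE)
    meta$fs_target <- bundle$target_motion$fs
  }
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a trial bundle from disk
#'
#' Reads a bundle directory written by [write_trial_bundle()]. Optional
#' streams (`target_motion`, `body_motion`, ground truth) that are absent on
#' disk come back as `NULL` fields; a bundle violating a type invariant
#' (e.g. `event_time` beyond the record end) is rejected with an error
#' naming the invariant.
#'
#' @param path bundle directory.
#' @return A [trial_bundle()].
#' @export
read_trial_bundle <- function(path) {
  if (!dir.exists(path)) stop("schema error: bundle directory not found: ", path)
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path)) stop("schema error: missing variable: metadata.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  wav_path <- file.path(path, "audio.wav")
  if (!file.exists(wav_path)) stop("schema error: missing variable: audio.wav")
  audio <- read_audio(wav_path, clip_level = meta$clip_level)
  if (!is.null(meta$fs_audio) && !isTRUE(all.equal(meta$fs_audio, audio$fs)))
    stop("schema error: metadata fs_audio disagrees with audio.wav header")
  body <- NULL
  bm_path <- file.path(path, "body_motion.csv")
  if (file.exists(bm_path)) {
    body <- df_to_motion(read.csv(bm_path), c("ax", "ay", "az"), "body_motion.csv")
    if (!is.null(meta$fs_accel)) body$fs <- meta$fs_accel
  }
  target <- NULL
  tm_path <- file.path(path, "target_motion.csv")
  if (file.exists(tm_path)) {
    target <- df_to_motion(read.csv(tm_path), c("ax", "ay"), "target_motion.csv")
    if (!is.null(meta$fs_target)) target$fs <- meta$fs_target
  }
  truth <- meta$ground_truth
  if (!is.null(truth) && length(truth) == 0L) truth <- NULL
  trial_bundle(audio = audio, body_motion = body, target_motion = target,
               species_preset = meta$species_preset,
               event_time = meta$event_time,
               ground_truth = truth,
               trial_id = meta$trial_id)
}
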