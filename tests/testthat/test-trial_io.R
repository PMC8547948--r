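# Bundle and WAV round trips, schema validation.

test_that("WAV files round-trip 16-bit PCM exactly", {
  fs <- 192e3
  x <- c(numeric(100), 0.5, -0.25, numeric(100))
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, fs, path)
  a <- read_audio(path)
  expect_equal(a$fs, fs)
  expect_equal(length(a$samples), length(x))
  # quantisation only: within one LSB of the original
  expect_lt(max(abs(a$samples - x)), 1 / 32767)
  # full-scale sample reads as 1.0 within one LSB
  write_wav(c(0, 1, 0), fs, path)
  expect_lt(abs(read_audio(path)$samples[2] - 1), 1 / 32767)
  # zeros round-trip identically
  write_wav(numeric(1000), 500e3, path)
  z <- read_audio(path)
  expect_identical(z$samples, numeric(1000))
  expect_equal(z$fs, 500e3)
})

test_that("stereo WAV input keeps channel 0 with a notice", {
  fs <- 48e3
  left <- seq(-0.5, 0.5, length.out = 64)
  right <- numeric(64)
  path <- withr::local_tempfile(fileext = ".wav")
  pcm <- as.integer(round(as.vector(rbind(left, right)) * 32767))
  con <- file(path, "wb")
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(pcm)), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(c(16L), con, size = 4, endian = "little")
  writeBin(c(1L, 2L), con, size = 2, endian = "little")
  writeBin(as.integer(c(fs, fs * 4)), con, size = 4, endian = "little")
  writeBin(c(4L, 16L), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(pcm)), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  close(con)
  expect_message(a <- read_audio(path), "channel 0")
  expect_equal(length(a$samples), 64)
  expect_lt(max(abs(a$samples - left)), 1 / 32767)
})

test_that("trial bundles round-trip through the directory format", {
  b <- simulate_trial(short_cfg(), trial_id = "rt1")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "trial_rt1")
  write_trial_bundle(b, path)
  b2 <- read_trial_bundle(path)
  expect_s3_class(b2, "trial_bundle")
  expect_identical(b2$trial_id, "rt1")
  expect_identical(b2$species_preset, "pp")
  expect_equal(b2$event_time, b$event_time)
  expect_equal(b2$audio$fs, b$audio$fs)
  # audio equal up to 16-bit quantisation
  expect_lt(max(abs(b2$audio$samples - b$audio$samples)), 1 / 32767)
  # motion and ground truth carried exactly (to numeric precision)
  expect_equal(unname(b2$body_motion$accel), unname(b$body_motion$accel),
               tolerance = 1e-12)
  expect_equal(b2$ground_truth$response_latency_ici,
               b$ground_truth$response_latency_ici)
  expect_equal(b2$ground_truth$click_times, b$ground_truth$click_times)

  # write/read/write: the second copy is semantically equal to the first
  path2 <- file.path(dir, "trial_rt1b")
  write_trial_bundle(b2, path2)
  b3 <- read_trial_bundle(path2)
  expect_identical(b3$audio$samples, b2$audio$samples)
  expect_equal(b3$ground_truth, b2$ground_truth)
})

test_that("optional streams are absent fields, not errors", {
  b <- simulate_trial(short_cfg(), trial_id = "opt")
  b$target_motion <- NULL
  dir <- withr::local_tempdir()
  path <- file.path(dir, "opt")
  write_trial_bundle(b, path)
  b2 <- read_trial_bundle(path)
  expect_null(b2$target_motion)
  expect_false(is.null(b2$body_motion))
})

test_that("schema violations are rejected with named errors", {
  b <- simulate_trial(short_cfg(), trial_id = "bad")
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bad")
  write_trial_bundle(b, path)
  # missing mandatory audio
  file.remove(file.path(path, "audio.wav"))
  expect_error(read_trial_bundle(path), "audio\\.wav")
  # event beyond record end
  path2 <- file.path(dir, "bad2")
  write_trial_bundle(b, path2)
  meta <- jsonlite::read_json(file.path(path2, "metadata.json"),
                              simplifyVector = TRUE)
  meta$event_time <- 99
  jsonlite::write_json(meta, file.path(path2, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(read_trial_bundle(path2), "event_time")
  # constructor-level invariants
  expect_error(audio_stream(numeric(0), 1000), "length")
  expect_error(audio_stream(c(0, NA), 1000), "finite")
  expect_error(sensor_stream(matrix(0, 5, 2), 100), "channels")
  expect_error(trial_bundle(b$audio, event_time = 99), "event_time")
})
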