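#' Species analysis presets
#'
#' Returns the per-species constants used throughout the pipeline: the
#' analysis band for bandpass filtering, the buzz ICI threshold and minimum
#' buzz duration, the ICI range used to clamp the simulator's control law,
#' the event-locked bin width, and default sampling/envelope rates.
#'
#' Presets follow the two study species: `"pp"`, the harbour porpoise
#' (*Phocoena phocoena*), with clicks near 130 kHz analysed in a
#' 100--250 kHz band, buzz ICI < 13 ms and 50 ms response bins; and `"md"`,
#' Blainville's beaked whale (*Mesoplodon densirostris*), with clicks near
#' 40 kHz analysed in 25--60 kHz, buzz ICI < 100 ms and 100 ms bins.
#'
#' @param preset `"pp"` or `"md"` (case-insensitive).
#' @return A list with elements `name`, `band` (Hz, length 2),
#'   `buzz_ici_max` (s), `buzz_min_duration` (s), `ici_min` (s),
#'   `bin_width` (s), `fs_audio` (Hz, default tag rate), `env_fs` (Hz,
#'   echogram envelope rate), `click_centre` (Hz), `click_cycles`.
#' @examples
#' species_preset("pp")$buzz_ici_max   # 0.013
#' species_preset("md")$band           # 25-60 kHz
#' @export
species_preset <- function(preset = c("pp", "md")) {
  preset <- tolower(preset[1L])
  preset <- match.arg(preset, c("pp", "md"))
  switch(preset,
    pp = list(
      name = "pp",
      band = c(100e3, 250e3),
      buzz_ici_max = 0.013,
      buzz_min_duration = 0.5,
      ici_min = 0.002,
      bin_width = 0.05,
      fs_audio = 576e3,
      fs_accel = 200,
      env_fs = 96e3,
      click_centre = 130e3,
      click_cycles = 10
    ),
    md = list(
      name = "md",
      band = c(25e3, 60e3),
      buzz_ici_max = 0.1,
      buzz_min_duration = 0.5,
      ici_min = 0.0035,
      bin_width = 0.1,
      fs_audio = 192e3,
      fs_accel = 50,
      env_fs = 48e3,
      click_centre = 40e3,
      click_cycles = 4
    )
  )
}
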