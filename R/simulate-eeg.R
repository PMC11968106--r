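#' Simulate EEG and EMG traces for a generated state sequence
#'
#' EEG is a sum of independent band-limited Gaussian noises (delta 0.5-4 Hz,
#' theta 6-9 Hz, sigma 10-15 Hz, plus a desynchronised 0.5-30 Hz background)
#' whose per-state weights follow the scoring criteria: delta-dominated NREM,
#' theta-dominated REM, desynchronised wake. EMG is 30-300 Hz noise with a
#' state-dependent envelope, high in wake and during microarousal bouts, low
#' in sleep. Envelopes are smoothed over ~0.5 s so that state transitions are
#' not spectrally sharp.
#'
#' @param params An [session_params()] object.
#' @param states Result of [generate_states()].
#' @return A list with `eeg` and `emg` tibbles (`t`, `value`; `fs` attribute).
#' @export
generate_eeg_emg <- function(params, states) {
  p <- params
  fs <- p$fs_eeg
  n <- as.integer(round(p$duration_s * fs))
  code <- state_codes(states, n, fs)

  bands <- list(
    delta = c(0.5, 4), theta = c(6, 9), sigma = c(10, 15), broad = c(0.5, 30)
  )
  w_smooth <- as.integer(0.5 * fs)
  eeg <- numeric(n)
  for (b in names(bands)) {
    noise <- band_limited_noise(n, fs, bands[[b]][1], bands[[b]][2])
    w <- p$band_powers[b, ][code]
    eeg <- eeg + noise * moving_average(w, w_smooth)
  }
  eeg <- eeg * p$eeg_scale

  carrier <- band_limited_noise(n, fs, 30, min(300, fs / 2 * 0.95))
  env <- p$emg_env[code]
  emg <- carrier * moving_average(env, as.integer(0.25 * fs)) * p$emg_scale

  list(
    eeg = new_signal_tbl(eeg, fs),
    emg = new_signal_tbl(emg, fs)
  )
}
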