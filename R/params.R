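#' Parameters for a synthetic recording session
#'
#' Builds the full parameter set consumed by [simulate_session()]. Presets
#' bundle the defaults used throughout the package's validation suite:
#'
#' * `"gc"` — granule-cell-like fiber photometry: NREM-gated infraslow
#'   oscillation (ISO) at 1.5 cycles/min, 29% of ISO cycles followed by a
#'   microarousal (MA) placed 6.06 s after the calcium decline onset.
#' * `"mc"` — mossy-cell-like: slightly lower ISO frequency (1.3 cycles/min),
#'   coupling 0.30, lag 5.18 s.
#' * `"sert"` — extracellular serotonin (GRAB-5-HT-like): phasic NREM peaks at
#'   1.14 cycles/min, 35% of peaks leading an MA by 6.82 s, state means
#'   ordered wake > NREM > REM.
#' * `"dual"` — simultaneous granule-cell site plus an antiphase second site
#'   (raphe-like), sharing a slow wake-state component so that wake activity
#'   correlates positively across sites while NREM activity anticorrelates.
#' * `"2p_gc"` / `"2p_mc"` — two-photon populations with 50%/22% (GC-like)
#'   or 28%/10% (MC-like) NREM-up/down-regulated cells.
#'
#' All probabilities must lie in \[0, 1\], rates/durations/frequencies must be
#' positive, microarousal durations are drawn strictly below 15 s (the MA
#' definition), and `frac_up + frac_down` must not exceed 1.
#'
#' @param preset Character; one of `"gc"`, `"mc"`, `"sert"`, `"dual"`,
#'   `"2p_gc"`, `"2p_mc"`.
#' @param duration_s Session length in seconds (>= 600).
#' @param ... Named overrides for any parameter listed in Details.
#'
#' @details Tunable fields (defaults in parentheses; z-units refer to the
#' latent signal before session z-scoring):
#' sampling rates `fs_eeg` (1017 Hz), `fs_photo` (100 Hz), `fs_2p` (10 Hz);
#' sleep architecture `state_dwell_means` (wake 150, NREM 180, REM 75 s),
#' `state_dwell_mins` (20/30/10 s), `p_rem` (0.5, probability a NREM bout ends
#' in REM); microarousals `ma_rate_per_min_nrem` (0.5), `ma_duration_range`
#' (5–12 s, always < 15 s); ISO `iso_freq_cpm` (1.5), `iso_amp_z` (1.5),
#' `iso_decline_s` (3), `iso_recover_s` (5), `iso_plateau_frac` (0.3),
#' `trough_ma_coupling_p` (0.29), `trough_to_ma_lag_s` (6.06, decline onset to
#' MA onset); serotonin `sert_peak_freq_cpm` (1.14), `sert_peak_ma_p` (0.35),
#' `sert_lead_ma_s` (6.82), `serotonin_antiphase`; latent state offsets
#' `state_offsets`; noise `noise_sd` (0.1 z), `noise_tau_s` (8 s); photometry
#' rendering `bleach_tau_s`, `artifact_sd`, `white_sd`, `f465_base`,
#' `f405_base`, `gain_465`, `gain_405`, `k_signal`; EEG synthesis
#' `band_powers` (4 bands x 4 states weight matrix), `emg_env`; two-photon
#' `n_cells`, `frac_up`, `frac_down`, `cell_rate_hz`, `up_gain`, `down_gain`,
#' `run_gain`, `transient_tau_s`, `transient_amp`, `motion_frac`.
#'
#' @return A list of class `"iso_params"`.
#' @export
#' @examples
#' p <- session_params("gc", duration_s = 900)
#' p$iso_freq_cpm
session_params <- function(preset = c("gc", "mc", "sert", "dual", "2p_gc", "2p_mc"),
                           duration_s = 3600, ...) {
  preset <- match.arg(preset)

  band_powers <- rbind(
    #          wake nrem rem  ma
    delta = c(0.7, 2.0, 0.4, 0.7),
    theta = c(0.7, 0.5, 1.8, 0.7),
    sigma = c(0.3, 0.8, 0.3, 0.3),
    broad = c(1.0, 0.4, 0.4, 1.0)
  )
  colnames(band_powers) <- c("wake", "nrem", "rem", "ma")

  p <- list(
    preset = preset,
    duration_s = duration_s,
    fs_eeg = 1017,
    fs_photo = 100,
    fs_2p = 10,
    state_dwell_means = c(wake = 150, nrem = 180, rem = 75),
    state_dwell_mins = c(wake = 20, nrem = 30, rem = 10),
    p_rem = 0.5,
    ma_rate_per_min_nrem = 0.5,
    ma_duration_range = c(5, 12),
    iso_freq_cpm = 1.5,
    iso_amp_z = 1.5,
    iso_decline_s = 3,
    iso_recover_s = 5,
    iso_plateau_frac = 0.3,
    trough_ma_coupling_p = 0.29,
    trough_to_ma_lag_s = 6.06,
    serotonin_antiphase = FALSE,
    sert_peak_freq_cpm = 1.14,
    sert_peak_ma_p = 0.35,
    sert_lead_ma_s = 6.82,
    state_offsets = c(wake = -0.5, nrem = 0.5, rem = 1.0),
    noise_sd = 0.1,
    noise_tau_s = 8,
    band_powers = band_powers,
    emg_env = c(wake = 1.0, nrem = 0.15, rem = 0.1, ma = 1.3),
    eeg_scale = 50,
    emg_scale = 30,
    bleach_tau_s = 36000,
    artifact_sd = 2.0,
    artifact_band = c(0.05, 0.5),
    white_sd = 0.3,
    f465_base = 100,
    f405_base = 80,
    gain_465 = 1.0,
    gain_405 = 0.8,
    k_signal = 0.05,
    wake_shared_sd = 0.4,
    n_cells = 200,
    frac_up = 0.50,
    frac_down = 0.22,
    cell_rate_hz = 0.06,
    up_gain = 4,
    down_gain = 0.25,
    run_gain = 2,
    transient_tau_s = 1.5,
    transient_amp = 25,
    motion_frac = 0.4
  )

  if (preset == "mc") {
    p$iso_freq_cpm <- 1.3
    p$trough_ma_coupling_p <- 0.30
    p$trough_to_ma_lag_s <- 5.18
  } else if (preset == "sert") {
    p$serotonin_antiphase <- TRUE
    p$state_offsets <- c(wake = 1.0, nrem = 0.0, rem = -1.5)
  } else if (preset == "dual") {
    p$serotonin_antiphase <- TRUE
  } else if (preset == "2p_mc") {
    p$frac_up <- 0.28
    p$frac_down <- 0.10
  }

  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      abort(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
    }
    p[names(dots)] <- dots
  }

  validate_params(p)
  structure(p, class = "iso_params")
}

validate_params <- function(p) {
  probs <- c(
    p_rem = p$p_rem, trough_ma_coupling_p = p$trough_ma_coupling_p,
    sert_peak_ma_p = p$sert_peak_ma_p, frac_up = p$frac_up,
    frac_down = p$frac_down, motion_frac = p$motion_frac
  )
  if (any(probs < 0 | probs > 1)) {
    abort("all probabilities must lie in [0, 1]")
  }
  pos <- c(
    p$duration_s, p$fs_eeg, p$fs_photo, p$fs_2p, p$state_dwell_means,
    p$iso_freq_cpm, p$sert_peak_freq_cpm, p$trough_to_ma_lag_s,
    p$sert_lead_ma_s, p$noise_tau_s, p$bleach_tau_s
  )
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    abort("rates, durations and frequencies must all be positive")
  }
  if (p$ma_rate_per_min_nrem < 0 || p$iso_amp_z < 0 || p$noise_sd < 0) {
    abort("ma_rate_per_min_nrem, iso_amp_z and noise_sd must be non-negative")
  }
  r <- p$ma_duration_range
  if (length(r) != 2 || r[1] <= 0 || r[2] < r[1] || r[2] >= 15) {
    abort("ma_duration_range must be 0 < low <= high < 15 s (microarousal definition)")
  }
  if (p$frac_up + p$frac_down > 1) {
    abort("frac_up + frac_down must not exceed 1")
  }
  invisible(p)
}

#' @export
print.iso_params <- function(x, ...) {
  cat(sprintf(
    "<iso_params> preset '%s', %.0f s session\n", x$preset, x$duration_s
  ))
  cat(sprintf(
    "  ISO %.2f cpm amp %.2f z | MA rate %.2f/min coupling %.2f lag %.2f s\n",
    x$iso_freq_cpm, x$iso_amp_z, x$ma_rate_per_min_nrem,
    x$trough_ma_coupling_p, x$trough_to_ma_lag_s
  ))
  invisible(x)
}
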