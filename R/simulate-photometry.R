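# Latent-trace construction and raw-channel rendering for the synthetic
# photometry presets.

# Piecewise-linear unit pulse train: 0 -> 1 over d_on seconds from each onset,
# 1 -> 0 over d_off. Returns a vector over n samples at rate fs.
pulse_shape <- function(onsets, n, fs, d_on, d_off) {
  shape <- numeric(n)
  if (!length(onsets)) {
    return(shape)
  }
  for (o in onsets) {
    i0 <- floor(o * fs) + 1L
    i1 <- floor((o + d_on) * fs)
    i2 <- floor((o + d_on + d_off) * fs)
    if (i0 > n) next
    up <- i0:min(i1, n)
    shape[up] <- pmax(shape[up], ((up - 1L) / fs - o) / d_on)
    if (i1 < n && i2 > i1) {
      dn <- (i1 + 1L):min(i2, n)
      shape[dn] <- pmax(shape[dn], 1 - ((dn - 1L) / fs - o - d_on) / d_off)
    }
  }
  pmin(shape, 1)
}

# Latent z-trace for one recording site.
# site = "calcium": state offsets + NREM plateau with ISO dips (troughs).
# site = "serotonin" / "raphe": phasic NREM peaks at the scheduled cycles.
latent_trace <- function(params, states, site = c("calcium", "serotonin", "raphe")) {
  site <- match.arg(site)
  p <- params
  fs <- p$fs_photo
  n <- as.integer(round(p$duration_s * fs))
  code <- state_codes(states, n, fs)

  offsets <- switch(site,
    calcium = p$state_offsets,
    serotonin = p$state_offsets,
    raphe = c(wake = 0.8, nrem = 0.0, rem = -1.0)
  )
  # microarousal samples keep the surrounding NREM offset: the infraslow
  # structure spans MAs and the state offset should not step inside a bout
  off_code <- code
  off_code[off_code == 4L] <- 2L
  base <- moving_average(offsets[off_code], as.integer(2 * fs))

  nrem_gate <- moving_average(as.numeric(off_code == 2L), as.integer(5 * fs))

  amp <- p$iso_amp_z
  shape <- pulse_shape(
    states$cycles$onset, n, fs, p$iso_decline_s, p$iso_recover_s
  )
  iso <- switch(site,
    calcium = nrem_gate * p$iso_plateau_frac * amp - amp * shape,
    serotonin = amp * shape,
    raphe = amp * shape - nrem_gate * p$iso_plateau_frac * amp
  )

  noise <- ou_noise(n, fs, p$noise_tau_s, p$noise_sd)
  base + iso + noise
}

# Render a latent z-trace into raw 465/405 channels: multiplicative
# exponential bleaching, a band-limited motion artifact shared by both
# channels (channel-specific gain), and white sensor noise. The 405 channel
# carries no activity, so the isosbestic regression can remove the shared
# structure.
render_photometry <- function(latent, params) {
  p <- params
  fs <- p$fs_photo
  n <- length(latent)
  t <- (seq_len(n) - 1L) / fs
  bleach <- exp(-t / p$bleach_tau_s)
  artifact <- band_limited_noise(n, fs, p$artifact_band[1], p$artifact_band[2]) *
    p$artifact_sd
  f465 <- p$f465_base * bleach * (1 + p$k_signal * latent) +
    p$gain_465 * artifact + rnorm(n, sd = p$white_sd)
  f405 <- p$f405_base * bleach +
    p$gain_405 * artifact + rnorm(n, sd = p$white_sd)
  out <- tibble(t = t, f465 = f465, f405 = f405)
  attr(out, "fs") <- fs
  out
}

#' Simulate dual-channel fiber photometry for a generated session
#'
#' Builds the latent z-trace for the requested site (state-dependent offsets,
#' NREM-gated ISO dips or serotonin-like phasic peaks at the scheduled cycle
#' times, slow Ornstein-Uhlenbeck noise) and renders it into raw 465/405
#' channels with shared bleaching and motion artifact.
#'
#' @param params An [session_params()] object.
#' @param states Result of [generate_states()].
#' @param site `"calcium"`, `"serotonin"`, or `"raphe"` (antiphase calcium).
#' @return A list: `photometry` tibble (`t`, `f465`, `f405`), `latent`
#'   (numeric latent z-trace at `fs_photo`).
#' @export
generate_photometry <- function(params, states, site = "calcium") {
  latent <- latent_trace(params, states, site)
  list(photometry = render_photometry(latent, params), latent = latent)
}

#' Simulate a serotonin (GRAB-5-HT-like) photometry session component
#'
#' Convenience wrapper around [generate_photometry()] with the serotonin
#' latent: state means ordered wake > NREM > REM, phasic NREM peaks at the
#' scheduled cycle times in antiphase to the calcium ISO, a programmed
#' fraction of peaks leading a microarousal.
#'
#' @inheritParams generate_photometry
#' @return See [generate_photometry()].
#' @export
generate_serotonin <- function(params, states) {
  generate_photometry(params, states, site = "serotonin")
}
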