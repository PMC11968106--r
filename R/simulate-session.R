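#' Simulate a complete synthetic recording session
#'
#' Orchestrates the generator: state architecture and microarousals, EEG/EMG,
#' photometry for the preset's site(s), and (for the two-photon presets) the
#' cell population and treadmill velocity. All randomness flows from `seed`,
#' so identical `(params, seed)` give bit-identical sessions.
#'
#' @param params An [session_params()] object.
#' @param seed Integer seed.
#' @return An object of class `"iso_session"`: a list with elements `params`,
#'   `seed`, `states` (ground-truth intervals / MAs / ISO cycle schedule),
#'   `eeg`, `emg`, `photometry` (and `latent`), for the `"dual"` preset also
#'   `photometry_b`/`latent_b`, and for the two-photon presets `cells`,
#'   `velocity`, `cell_labels`.
#' @export
#' @examples
#' s <- simulate_session(session_params("gc", duration_s = 900), seed = 1)
#' names(s)
simulate_session <- function(params, seed = 1) {
  stopifnot(inherits(params, "iso_params"))
  set.seed(as.integer(seed))
  p <- params

  states <- generate_states(p)
  sig <- generate_eeg_emg(p, states)

  out <- list(
    params = p, seed = as.integer(seed), states = states,
    eeg = sig$eeg, emg = sig$emg
  )

  if (p$preset %in% c("gc", "mc")) {
    ph <- generate_photometry(p, states, site = "calcium")
    out$photometry <- ph$photometry
    out$latent <- ph$latent
  } else if (p$preset == "sert") {
    ph <- generate_photometry(p, states, site = "serotonin")
    out$photometry <- ph$photometry
    out$latent <- ph$latent
  } else if (p$preset == "dual") {
    fs <- p$fs_photo
    n <- as.integer(round(p$duration_s * fs))
    lat_a <- latent_trace(p, states, "calcium")
    lat_b <- latent_trace(p, states, "raphe")
    # slow arousal-linked component shared by both sites during wake, so the
    # two sites correlate positively in wake and antiphase (via the ISO) in
    # NREM
    code <- state_codes(states, n, fs)
    wake_gate <- moving_average(as.numeric(code == 1L), as.integer(5 * fs))
    shared <- ou_noise(n, fs, 10, p$wake_shared_sd) * wake_gate
    lat_a <- lat_a + shared
    lat_b <- lat_b + shared
    out$photometry <- render_photometry(lat_a, p)
    out$photometry_b <- render_photometry(lat_b, p)
    out$latent <- lat_a
    out$latent_b <- lat_b
  } else if (p$preset %in% c("2p_gc", "2p_mc")) {
    tp <- generate_twophoton(p, states)
    out$cells <- tp$cells
    out$velocity <- tp$velocity
    out$cell_labels <- tp$labels
  }

  structure(out, class = "iso_session")
}

#' @export
print.iso_session <- function(x, ...) {
  cat(sprintf(
    "<iso_session> preset '%s', %.0f s, seed %d\n",
    x$params$preset, x$params$duration_s, x$seed
  ))
  cat(sprintf(
    "  %d state intervals, %d MAs, %d ISO cycles\n",
    nrow(x$states$intervals), nrow(x$states$ma), nrow(x$states$cycles)
  ))
  invisible(x)
}
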