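# Infraslow spectral quantification on the 1 Hz z-scored dF/F trace.

#' Infraslow sliding-window spectrogram (cycles/min)
#'
#' FFT power over a 2 min window stepped by 2 s on the 1 Hz trace, reported
#' over 0-6 cycles/min (0-0.1 Hz). Windows are mean-removed and
#' Hann-tapered, which suppresses leakage from the state-offset steps at
#' epoch boundaries.
#'
#' @param z1hz A 1 Hz `dff_signal` (see [downsample_1hz()]) or numeric
#'   vector; the `z` column is used.
#' @param window_s,step_s Window and hop in seconds (defaults 120 / 2).
#' @param max_cpm Upper frequency bound in cycles/min (default 6).
#' @return A `spectrogram` object whose `freqs` are in cycles/min.
#' @export
iso_spectrogram <- function(z1hz, window_s = 120, step_s = 2, max_cpm = 6) {
  v <- if (is.data.frame(z1hz)) pull_signal(z1hz, "z") else as.numeric(z1hz)
  if (length(v) < window_s) {
    abort("signal shorter than one 2 min window: need at least 120 s at 1 Hz")
  }
  sp <- compute_spectrogram(v, fs = 1,
    window_s = window_s, step_s = step_s, max_freq = max_cpm / 60
  )
  if (is.data.frame(z1hz) && "t" %in% names(z1hz)) {
    sp$times <- sp$times + z1hz$t[1]
  }
  sp$freqs <- sp$freqs * 60
  sp$unit <- "cpm"
  sp
}

# Fraction of each 2 min window's span carrying the given state.
window_state_occupancy <- function(spec, hyp, state, include_ma = TRUE) {
  bin_s <- attr(hyp, "bin_s") %||% 2
  match_state <- if (identical(state, "nrem") && include_ma) c("nrem", "ma") else state
  flag <- as.numeric(hyp$state %in% match_state)
  half <- spec$window_s / 2
  vapply(spec$times, function(tc) {
    i0 <- max(1L, floor((tc - half) / bin_s) + 1L)
    i1 <- min(nrow(hyp), ceiling((tc + half) / bin_s))
    if (i1 < i0) {
      return(0)
    }
    mean(flag[i0:i1])
  }, numeric(1))
}

#' State-resolved infraslow spectrum and relative 1-2 cycles/min power
#'
#' A window contributes to a state when at least `occupancy` of its span
#' carries that state's label (MA bins count as NREM by default — the ISO
#' spans microarousals). The state spectrum is the mean over its windows;
#' `rel_band_power` is power in `band` (default 1-2 cycles/min) divided by
#' total power over `total` (default 0-6 cycles/min), both excluding the DC
#' bin. States with no qualifying window get `NA` rather than an error.
#'
#' @param spec An [iso_spectrogram()] result.
#' @param hyp A hypnogram covering the trace.
#' @param states States to summarise.
#' @param band,total Band and normalisation range, cycles/min.
#' @param occupancy Minimum state occupancy of a window (default 0.8).
#' @param include_ma Count MA bins as NREM context.
#' @return A tibble with one row per state: `state`, `n_windows`,
#'   `rel_band_power`; the per-state mean spectra are attached as the
#'   `spectra` attribute (long tibble `state`, `freq_cpm`, `power`).
#' @export
state_iso_power <- function(spec, hyp, states = c("wake", "nrem", "rem"),
                            band = c(1, 2), total = c(0, 6),
                            occupancy = 0.8, include_ma = TRUE) {
  stopifnot(inherits(spec, "spectrogram"))
  nondc <- spec$freqs > 1e-9
  in_band <- nondc & spec$freqs >= band[1] & spec$freqs <= band[2]
  in_total <- nondc & spec$freqs >= total[1] & spec$freqs <= total[2]

  spectra <- list()
  rows <- purrr::map_dfr(states, function(st) {
    occ <- window_state_occupancy(spec, hyp, st, include_ma)
    sel <- occ >= occupancy
    if (!any(sel)) {
      return(tibble(state = st, n_windows = 0L, rel_band_power = NA_real_))
    }
    m <- colMeans(spec$power[sel, , drop = FALSE])
    spectra[[st]] <<- tibble(state = st, freq_cpm = spec$freqs, power = m)
    tibble(
      state = st, n_windows = sum(sel),
      rel_band_power = sum(m[in_band]) / sum(m[in_total])
    )
  })
  attr(rows, "spectra") <- dplyr::bind_rows(spectra)
  rows
}

# NREM epochs as (start, end) intervals from a hypnogram; MA bins bridge an
# epoch rather than splitting it.
nrem_epochs <- function(hyp) {
  bin_s <- attr(hyp, "bin_s") %||% 2
  runs <- index_runs(hyp$state %in% c("nrem", "ma"))
  runs <- runs[runs$value, , drop = FALSE]
  keep <- vapply(seq_len(nrow(runs)), function(i) {
    any(hyp$state[runs$start[i]:runs$end[i]] == "nrem")
  }, logical(1))
  runs <- runs[keep, , drop = FALSE]
  tibble(
    start = hyp$bin_start[runs$start],
    end = hyp$bin_end[runs$end]
  )
}

#' Infraslow power and amplitude at NREM stages T0, T1, T2
#'
#' T1 is the first minute of every NREM epoch; T2 the last minute of epochs
#' at least 2 min long; T0 the first minute of epochs preceded by more than
#' `prior_wake_s` of contiguous wakefulness. Per minute, `power` is the mean
#' 1-2 cycles/min periodogram power of the minute and `amplitude` the
#' peak-to-trough range of the 1-2 cycles/min band-passed z-trace within the
#' minute. Epochs shorter than 2 min contribute T0/T1 only.
#'
#' @param z1hz A 1 Hz `dff_signal`.
#' @param hyp A hypnogram.
#' @param prior_wake_s Wake duration defining a "first" NREM epoch (s).
#' @return A tibble: `epoch`, `stage` (T0/T1/T2), `start_s`, `power`,
#'   `amplitude`.
#' @export
stage_analysis <- function(z1hz, hyp, prior_wake_s = 300) {
  z <- pull_signal(z1hz, "z")
  t0 <- if (is.data.frame(z1hz) && "t" %in% names(z1hz)) floor(z1hz$t[1]) else 0
  epochs <- nrem_epochs(hyp)
  if (!nrow(epochs)) {
    return(tibble(
      epoch = integer(0), stage = character(0), start_s = numeric(0),
      power = numeric(0), amplitude = numeric(0)
    ))
  }

  # 1-2 cycles/min band-pass of the whole trace for the amplitude measure
  bf <- signal::butter(2, c(1, 2) / 60 / 0.5, type = "pass")
  zbp <- as.numeric(signal::filtfilt(bf, z))

  # contiguous wake immediately before each epoch
  bin_s <- attr(hyp, "bin_s") %||% 2
  wake_before <- vapply(epochs$start, function(s) {
    i <- floor(s / bin_s)
    k <- 0L
    while (i - k >= 1L && hyp$state[i - k] == "wake") k <- k + 1L
    k * bin_s
  }, numeric(1))

  minute_row <- function(ep, stage, seg_start) {
    i0 <- max(1L, floor(seg_start - t0) + 1L)
    i1 <- min(length(z), i0 + 59L)
    if (i1 - i0 + 1L < 60L) {
      return(NULL)
    }
    seg <- z[i0:i1]
    w <- 0.5 - 0.5 * cos(2 * pi * (0:59) / 59)
    xw <- (seg - mean(seg)) * w
    pw <- Mod(fft(xw))^2 / (60 * sum(w^2))
    f_cpm <- (0:30) * 1 / 60 * 60 # one-sided bins, cycles/min
    sel <- f_cpm >= 1 & f_cpm <= 2
    tibble(
      epoch = ep, stage = stage, start_s = seg_start,
      power = mean(pw[seq_len(31)][sel]),
      amplitude = diff(range(zbp[i0:i1]))
    )
  }

  out <- purrr::map_dfr(seq_len(nrow(epochs)), function(i) {
    dur <- epochs$end[i] - epochs$start[i]
    if (dur < 60) {
      return(NULL)
    }
    rows <- list(minute_row(i, "T1", epochs$start[i]))
    if (wake_before[i] > prior_wake_s) {
      rows <- c(rows, list(minute_row(i, "T0", epochs$start[i])))
    }
    if (dur >= 120) {
      rows <- c(rows, list(minute_row(i, "T2", epochs$end[i] - 60)))
    }
    dplyr::bind_rows(rows)
  })
  out
}

#' Lagged correlation between the z-trace and EEG sigma-band power in NREM
#'
#' Pearson correlation between the 1 Hz z-trace and the sigma-band power
#' time course at lags up to +/-`max_lag_s`, restricted to sample pairs that
#' both fall in NREM.
#'
#' @param z1hz A 1 Hz `dff_signal`.
#' @param eeg_spec EEG spectrogram from [compute_spectrogram()] (freqs in Hz).
#' @param hyp A hypnogram.
#' @param band Sigma band in Hz (default 10-15).
#' @param max_lag_s Maximum lag (s).
#' @param include_ma Count MA bins as NREM.
#' @return A tibble: `lag_s`, `r`, `n` (positive lag = sigma delayed
#'   relative to z).
#' @export
sigma_crosscorr <- function(z1hz, eeg_spec, hyp, band = c(10, 15),
                            max_lag_s = 60, include_ma = TRUE) {
  sigma <- band_power(eeg_spec, band)
  # common 2 s grid at the spectrogram window centers
  tt <- eeg_spec$times
  zt <- if (is.data.frame(z1hz) && "t" %in% names(z1hz)) z1hz$t else seq_along(pull_signal(z1hz, "z")) - 0.5
  zv <- approx(zt, pull_signal(z1hz, "z"), xout = tt, rule = 2)$y
  st <- state_at(hyp, tt)
  ok_state <- if (include_ma) st %in% c("nrem", "ma") else st == "nrem"

  step <- eeg_spec$step_s
  lags <- seq(-max_lag_s, max_lag_s, by = step)
  n <- length(tt)
  out <- purrr::map_dfr(lags, function(lg) {
    k <- as.integer(round(lg / step))
    if (k >= 0) {
      i <- seq_len(n - k)
      j <- i + k
    } else {
      j <- seq_len(n + k)
      i <- j - k
    }
    use <- ok_state[i] & ok_state[j]
    if (sum(use) < 10) {
      return(tibble(lag_s = lg, r = NA_real_, n = sum(use)))
    }
    tibble(lag_s = lg, r = cor(zv[i[use]], sigma[j[use]]), n = sum(use))
  })
  out
}
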