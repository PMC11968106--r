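# Sleep scoring: wake/NREM/REM classification on a 2 s bin grid from the
# EEG spectrogram and the EMG envelope, plus microarousal detection.

new_hypnogram <- function(bin_start, state, bin_s, ma_intervals = NULL,
                          thresholds = NULL) {
  out <- tibble(
    bin_start = bin_start,
    bin_end = bin_start + bin_s,
    state = state
  )
  class(out) <- c("hypnogram", class(out))
  attr(out, "bin_s") <- bin_s
  attr(out, "ma_intervals") <-
    ma_intervals %||% tibble(start = numeric(0), end = numeric(0), onset = numeric(0))
  attr(out, "thresholds") <- thresholds
  out
}

#' Microarousal intervals of a hypnogram
#'
#' @param hyp A hypnogram from [score_states()] / [detect_microarousals()].
#' @return Tibble with columns `start`, `end` (bout bounds in seconds) and
#'   `onset` (first suprathreshold EMG time inside the bout).
#' @export
ma_intervals <- function(hyp) {
  attr(hyp, "ma_intervals") %||%
    tibble(start = numeric(0), end = numeric(0), onset = numeric(0))
}

#' State label at arbitrary times
#'
#' @param hyp A hypnogram.
#' @param times Numeric vector of times (s).
#' @return Character vector of per-time labels; times beyond the hypnogram
#'   give NA.
#' @export
state_at <- function(hyp, times) {
  bin_s <- attr(hyp, "bin_s") %||% 2
  idx <- floor(times / bin_s) + 1L
  out <- rep(NA_character_, length(times))
  ok <- idx >= 1L & idx <= nrow(hyp)
  out[ok] <- hyp$state[idx[ok]]
  out
}

#' Score wake/NREM/REM from EEG and EMG
#'
#' Deterministic per-bin decision rule on 2 s bins: a bin is wake when its
#' EMG RMS exceeds the EMG threshold; otherwise REM when the theta/delta
#' power ratio exceeds `td_thresh`, else NREM. Single-bin label flicker is
#' then removed (a bin flanked by two agreeing, differing bins takes the
#' flanking label), and microarousals are detected with
#' [detect_microarousals()].
#'
#' The default EMG threshold separates the bimodal per-bin RMS distribution
#' with a deterministic two-means split on log RMS (threshold at the
#' geometric mean of the two cluster centers), which is robust to the
#' session's wake fraction; both thresholds can be overridden. The
#' spectrogram uses a 5 s window stepped by 2 s.
#'
#' @param eeg,emg Numeric vectors or `t`/`value` tibbles.
#' @param fs_eeg,fs_emg Sampling rates (Hz); inferred from tibbles.
#' @param bands Band edges from [eeg_bands()].
#' @param emg_thresh EMG RMS threshold; default: two-means cluster split.
#' @param td_thresh Theta/delta ratio threshold for REM.
#' @param bin_s Bin width in seconds.
#' @param smooth Remove single-bin label flicker before bout extraction.
#' @param detect_ma Run microarousal detection.
#' @return A `hypnogram` tibble: `bin_start`, `bin_end`, `state` (one of
#'   `"wake"`, `"nrem"`, `"rem"`, `"ma"`), with attributes `ma_intervals`
#'   (see [ma_intervals()]) and `thresholds`.
#' @export
score_states <- function(eeg, emg, fs_eeg = NULL, fs_emg = NULL,
                         bands = eeg_bands(), emg_thresh = NULL,
                         td_thresh = 1.5, bin_s = 2,
                         smooth = TRUE, detect_ma = TRUE) {
  fs_eeg <- signal_fs(eeg, fs_eeg)
  fs_emg <- signal_fs(emg, fs_emg)
  eeg_v <- pull_signal(eeg)
  emg_v <- pull_signal(emg)
  ts_check(eeg_v, fs_eeg, "eeg")
  ts_check(emg_v, fs_emg, "emg")
  if (sd(emg_v) == 0) {
    abort(paste(
      "EMG is constant: per-session percentile thresholds are undefined;",
      "supply `emg_thresh` explicitly"
    ))
  }

  spec <- compute_spectrogram(eeg_v, fs_eeg,
    window_s = 5, step_s = bin_s, max_freq = 30
  )
  delta <- band_power(spec, bands$delta)
  theta <- band_power(spec, bands$theta)

  dur <- min(length(eeg_v) / fs_eeg, length(emg_v) / fs_emg)
  n_bins <- as.integer(floor(dur / bin_s))
  spb <- as.integer(round(bin_s * fs_emg))
  emg_rms <- sqrt(colMeans(matrix(
    emg_v[seq_len(n_bins * spb)]^2,
    nrow = spb
  )))

  win_idx <- pmin(seq_len(n_bins), length(delta))
  delta <- delta[win_idx]
  theta <- theta[win_idx]

  emg_thresh <- emg_thresh %||% emg_cluster_threshold(emg_rms)
  state <- ifelse(
    emg_rms > emg_thresh, "wake",
    ifelse(theta / pmax(delta, .Machine$double.eps) > td_thresh, "rem", "nrem")
  )

  if (smooth && n_bins >= 3L) {
    i <- 2:(n_bins - 1L)
    flick <- state[i - 1L] == state[i + 1L] & state[i] != state[i - 1L]
    state[i][flick] <- state[i - 1L][flick]
  }

  hyp <- new_hypnogram(
    bin_start = (seq_len(n_bins) - 1L) * bin_s,
    state = state, bin_s = bin_s,
    thresholds = list(emg_thresh = emg_thresh, td_thresh = td_thresh)
  )
  if (detect_ma) {
    hyp <- detect_microarousals(hyp, emg_v, fs_emg)
  }
  hyp
}

# Deterministic two-means split of the (log) per-bin EMG RMS: centers are
# initialised at the 10th/90th percentiles and iterated to convergence; the
# threshold is the geometric mean of the final centers.
emg_cluster_threshold <- function(rms) {
  lx <- log(pmax(rms, .Machine$double.eps))
  c1 <- unname(quantile(lx, 0.1))
  c2 <- unname(quantile(lx, 0.9))
  for (i in 1:50) {
    assign2 <- abs(lx - c2) < abs(lx - c1)
    n1 <- c1
    n2 <- c2
    if (any(!assign2)) n1 <- mean(lx[!assign2])
    if (any(assign2)) n2 <- mean(lx[assign2])
    if (abs(n1 - c1) + abs(n2 - c2) < 1e-10) break
    c1 <- n1
    c2 <- n2
  }
  exp((c1 + c2) / 2)
}

#' Detect microarousals in a scored hypnogram
#'
#' Wake bouts shorter than 15 s flanked by NREM on both sides are candidate
#' microarousals; a candidate is confirmed when the EMG envelope (RMS in
#' short 0.2 s windows, keeping the onset estimate sharp) exceeds mean + `thresh_sd` * SD of the envelope inside the
#' bout. Confirmed bouts are relabelled `"ma"` and their intervals recorded,
#' with the onset placed at the first suprathreshold envelope sample. Wake
#' bouts flanked by REM are left as wake.
#'
#' @param hyp A hypnogram from [score_states()].
#' @param emg EMG trace (vector or `t`/`value` tibble) covering the hypnogram.
#' @param fs_emg EMG sampling rate (Hz).
#' @param thresh_sd EMG threshold in envelope SD units above the envelope
#'   mean (default 0.5).
#' @param max_dur_s Maximum bout duration in seconds (exclusive; default 15).
#' @param envelope_s RMS envelope window (s).
#' @return The hypnogram with MA bins relabelled and the `ma_intervals`
#'   attribute populated.
#' @export
detect_microarousals <- function(hyp, emg, fs_emg = NULL, thresh_sd = 0.5,
                                 max_dur_s = 15, envelope_s = 0.2) {
  fs_emg <- signal_fs(emg, fs_emg)
  emg_v <- pull_signal(emg)
  bin_s <- attr(hyp, "bin_s") %||% 2

  env <- sqrt(pmax(moving_average(emg_v^2, envelope_s * fs_emg), 0))
  thr <- mean(env) + thresh_sd * sd(env)

  state <- hyp$state
  runs <- index_runs(state)
  iv <- tibble(start = numeric(0), end = numeric(0), onset = numeric(0))
  for (i in seq_len(nrow(runs))) {
    if (runs$value[i] != "wake") next
    dur <- (runs$end[i] - runs$start[i] + 1L) * bin_s
    if (dur >= max_dur_s) next
    if (i == 1L || i == nrow(runs)) next
    if (runs$value[i - 1L] != "nrem" || runs$value[i + 1L] != "nrem") next
    t0 <- hyp$bin_start[runs$start[i]]
    t1 <- hyp$bin_end[runs$end[i]]
    a <- max(1L, floor(t0 * fs_emg) + 1L)
    b <- min(length(env), ceiling(t1 * fs_emg))
    if (b < a) next
    sup <- which(env[a:b] > thr)
    if (!length(sup)) next
    onset <- (a + sup[1L] - 2L) / fs_emg
    state[runs$start[i]:runs$end[i]] <- "ma"
    iv <- dplyr::bind_rows(iv, tibble(start = t0, end = t1, onset = onset))
  }

  new_hypnogram(
    bin_start = hyp$bin_start, state = state, bin_s = bin_s,
    ma_intervals = iv, thresholds = attr(hyp, "thresholds")
  )
}

#' Per-state total durations and microarousal statistics
#'
#' @param hyp A hypnogram.
#' @param include_ma_in_nrem Count MA time toward the NREM denominator of the
#'   MA frequency (default TRUE: microarousals are NREM-context events).
#' @return A one-row tibble: seconds of wake/NREM/REM/MA, `ma_count`, and
#'   `ma_per_h_nrem` (events per hour of NREM).
#' @export
state_durations <- function(hyp, include_ma_in_nrem = TRUE) {
  bin_s <- attr(hyp, "bin_s") %||% 2
  secs <- function(s) sum(hyp$state == s) * bin_s
  nrem_ctx_s <- secs("nrem") + if (include_ma_in_nrem) secs("ma") else 0
  n_ma <- nrow(ma_intervals(hyp))
  tibble(
    wake_s = secs("wake"), nrem_s = secs("nrem"), rem_s = secs("rem"),
    ma_s = secs("ma"), ma_count = n_ma,
    ma_per_h_nrem = if (nrem_ctx_s > 0) n_ma / (nrem_ctx_s / 3600) else NA_real_
  )
}

#' Plot a hypnogram as a state ribbon
#'
#' @param object A hypnogram.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hypnogram <- function(object, ...) {
  lv <- c(wake = 3, ma = 2.5, rem = 2, nrem = 1)
  df <- tibble(
    t = object$bin_start, level = lv[object$state], state = object$state
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$level)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$state == "ma"),
      ggplot2::aes(colour = .data$state), size = 0.8
    ) +
    ggplot2::scale_y_continuous(
      breaks = unname(lv[c("nrem", "rem", "wake")]),
      labels = c("NREM", "REM", "wake")
    ) +
    ggplot2::labs(x = "time (s)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
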