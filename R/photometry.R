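# Isosbestic dF/F preprocessing of dual-channel fiber photometry.

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`), so
#' the passband has unit gain and zero phase shift — phase distortion here
#' would bias every downstream latency estimate.
#'
#' @param x Numeric vector or `t`/`value` tibble.
#' @param fs Sampling rate (Hz).
#' @param cutoff Cutoff frequency (Hz), default 2.
#' @param order Filter order (default 4).
#' @return Numeric vector (same length as input).
#' @export
lowpass_filter <- function(x, fs = NULL, cutoff = 2, order = 4) {
  fs <- signal_fs(x, fs)
  v <- pull_signal(x)
  ts_check(v, fs)
  if (cutoff >= fs / 2) {
    abort(sprintf(
      "cutoff (%g Hz) must be below the Nyquist frequency (%g Hz)", cutoff, fs / 2
    ))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # reflect the signal at both ends before filtering: filtfilt itself does
  # not pad, and its edge transients can be large enough to corrupt the
  # reference fit
  pad <- min(length(v) - 1L, as.integer(ceiling(3 * fs / cutoff)))
  vp <- c(
    2 * v[1] - v[(pad + 1L):2L],
    v,
    2 * v[length(v)] - v[(length(v) - 1L):(length(v) - pad)]
  )
  out <- as.numeric(signal::filtfilt(bf, vp))
  out[(pad + 1L):(pad + length(v))]
}

#' Least-squares fit of the isosbestic reference channel
#'
#' Fits the activity-independent baseline F0 used by [compute_dff()] by
#' ordinary least squares on the reference channel:
#' `f465 ~ slope * f405 + intercept (+ trend * t)`. The optional linear time
#' term (default on) absorbs the channel-specific component of slow
#' photobleaching; without it, any chance correlation between the activity
#' signal and the monotone bleach corrupts the fitted slope and leaks the
#' shared motion artifact into dF/F. Both channels should already be
#' low-pass filtered. With an exact linear relation between the channels the
#' trend coefficient is zero and the classical two-parameter fit is
#' recovered.
#'
#' @param f465,f405 Numeric vectors of equal length (signal and reference).
#' @param detrend Include the linear time regressor (default TRUE).
#' @return List with `f0` (fitted baseline), `slope`, `intercept`, `trend`
#'   (0 when `detrend = FALSE`).
#' @export
fit_reference <- function(f465, f405, detrend = TRUE) {
  if (length(f465) != length(f405)) {
    abort("f465 and f405 must have equal length")
  }
  if (sd(f405) == 0) {
    abort("reference channel f405 is constant: the least-squares fit is degenerate")
  }
  if (detrend) {
    tt <- seq_along(f405) / length(f405)
    fit <- stats::lm.fit(cbind(1, f405, tt), f465)
    co <- fit$coefficients
    list(
      f0 = as.numeric(fit$fitted.values), slope = unname(co[2]),
      intercept = unname(co[1]), trend = unname(co[3])
    )
  } else {
    slope <- stats::cov(f465, f405) / stats::var(f405)
    intercept <- mean(f465) - slope * mean(f405)
    list(
      f0 = slope * f405 + intercept, slope = slope,
      intercept = intercept, trend = 0
    )
  }
}

#' dF/F and per-session z-score from signal and fitted baseline
#'
#' `dff = (F - F0) / F0` elementwise; `z` is the session z-score of dff
#' (mean 0, SD 1 by construction).
#'
#' @param f465 Signal channel (numeric).
#' @param f0 Fitted baseline from [fit_reference()] (numeric, all > 0).
#' @param fs Sampling rate (Hz).
#' @param t0 Time of the first sample (s).
#' @return A `dff_signal` tibble with columns `t`, `dff`, `z` and attributes
#'   `fs`, `fit` (if attached by [process_photometry()]).
#' @export
compute_dff <- function(f465, f0, fs, t0 = 0) {
  bad <- which(f0 <= 0)
  if (length(bad)) {
    abort(sprintf(
      "fitted baseline F0 is non-positive at t = %.3f s (sample %d)",
      t0 + (bad[1] - 1) / fs, bad[1]
    ))
  }
  dff <- (f465 - f0) / f0
  s <- sd(dff)
  z <- if (s == 0) dff * 0 else (dff - mean(dff)) / s
  out <- tibble(t = t0 + (seq_along(dff) - 1L) / fs, dff = dff, z = z)
  class(out) <- c("dff_signal", class(out))
  attr(out, "fs") <- fs
  out
}

#' Full photometry preprocessing: filter, isosbestic fit, dF/F, z-score
#'
#' The two raw channels are low-pass filtered at `cutoff` Hz, the filtered
#' 405 nm reference is least-squares fitted to the filtered 465 nm signal,
#' and dF/F = (F - F0)/F0 with F0 the fitted reference; dF/F is then
#' z-scored over the session. Filtering precedes the fit.
#'
#' @param photo Tibble with columns `t`, `f465`, `f405`.
#' @param fs Sampling rate (Hz); inferred from `t` if absent.
#' @param cutoff Low-pass cutoff (Hz).
#' @return A `dff_signal` tibble (`t`, `dff`, `z`) with attributes `fs` and
#'   `fit` (list: `slope`, `intercept`).
#' @export
#' @examples
#' s <- simulate_session(session_params("gc", duration_s = 900), seed = 1)
#' d <- process_photometry(s$photometry)
#' c(mean(d$z), sd(d$z))
process_photometry <- function(photo, fs = NULL, cutoff = 2) {
  if (!all(c("f465", "f405") %in% names(photo))) {
    abort("`photo` must have columns f465 and f405")
  }
  fs <- signal_fs(photo, fs)
  f465 <- lowpass_filter(photo$f465, fs, cutoff)
  f405 <- lowpass_filter(photo$f405, fs, cutoff)
  fit <- fit_reference(f465, f405)
  t0 <- if ("t" %in% names(photo)) photo$t[1] else 0
  out <- compute_dff(f465, fit$f0, fs, t0 = t0)
  attr(out, "fit") <- list(slope = fit$slope, intercept = fit$intercept)
  out
}

#' Downsample a dF/F signal to 1 Hz by block averaging
#'
#' Non-overlapping 1 s block means (anti-aliasing by construction at the
#' infraslow frequencies of interest). The z column is re-standardised after
#' averaging so the per-session z invariant (mean 0, SD 1) holds on the
#' 1 Hz series as well.
#'
#' @param sig A `dff_signal` tibble from [process_photometry()], or any
#'   tibble with `t` plus `dff` and/or `z` columns.
#' @param fs Sampling rate (Hz) of the input.
#' @return A `dff_signal` tibble at 1 Hz (`t` at block centers).
#' @export
downsample_1hz <- function(sig, fs = NULL) {
  fs <- signal_fs(sig, fs)
  if (fs < 1) {
    abort("input must be sampled at >= 1 Hz")
  }
  spb <- as.integer(round(fs))
  v <- if ("dff" %in% names(sig)) sig$dff else pull_signal(sig, "z")
  n_blk <- floor(length(v) / spb)
  if (n_blk < 2) {
    abort("signal too short to downsample to 1 Hz")
  }
  m <- colMeans(matrix(v[seq_len(n_blk * spb)], nrow = spb))
  t0 <- if ("t" %in% names(sig)) sig$t[1] else 0
  s <- sd(m)
  z <- if (s == 0) m * 0 else (m - mean(m)) / s
  out <- tibble(t = t0 + (seq_len(n_blk) - 1L) + 0.5, dff = m, z = z)
  class(out) <- c("dff_signal", class(out))
  attr(out, "fs") <- 1
  attr(out, "fit") <- attr(sig, "fit")
  out
}
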