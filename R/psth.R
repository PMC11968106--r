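# Microarousal-aligned PSTH and the latency/drop quantification.

#' Event-aligned average trace (PSTH)
#'
#' Aligns the signal to each event onset (typically microarousal onsets) and
#' averages the snippets on a common time grid. Events whose window extends
#' beyond the recorded session are dropped. Snippets keep their own
#' session-z units: no per-event re-normalisation.
#'
#' @param z A `dff_signal` (any rate; use the full-rate trace for latency
#'   work).
#' @param onsets Event onset times (s), e.g. `ma_intervals(hyp)$onset`.
#' @param pre_s,post_s Window before/after onset (s).
#' @param fs Sampling rate (Hz).
#' @return A `psth` object: list with `time` (s relative to onset), `mean`,
#'   `n_events`, `sd_ref` (session SD of z), `fs`.
#' @export
psth <- function(z, onsets, pre_s = 15, post_s = 15, fs = NULL) {
  fs <- signal_fs(z, fs)
  zv <- if (is.data.frame(z) && "z" %in% names(z)) z$z else pull_signal(z)
  t0 <- if (is.data.frame(z) && "t" %in% names(z)) z$t[1] else 0
  n <- length(zv)

  k_pre <- as.integer(round(pre_s * fs))
  k_post <- as.integer(round(post_s * fs))
  idx0 <- round((onsets - t0) * fs) + 1L
  ok <- idx0 - k_pre >= 1L & idx0 + k_post <= n
  idx0 <- idx0[ok]
  if (!length(idx0)) {
    abort("no event has a full PSTH window inside the session")
  }

  rel <- (-k_pre):k_post
  snips <- vapply(idx0, function(i) zv[i + rel], numeric(length(rel)))
  structure(
    list(
      time = rel / fs,
      mean = rowMeans(snips),
      n_events = length(idx0),
      sd_ref = sd(zv),
      fs = fs
    ),
    class = "psth"
  )
}

#' Latency and drop from an event-aligned PSTH
#'
#' The baseline is the mean trace over `baseline_window` (default -15 to
#' -5 s before the aligned onset). The trace extremum (minimum for
#' `direction = "down"`, maximum for `"up"`) is located, and the
#' decline/rise onset is the last pre-extremum time at which the deviation
#' from baseline was still within `thresh_sd * sd_ref`; the exact crossing
#' is linearly interpolated, making the estimator exact on noise-free
#' piecewise-linear declines. Latency is the time from that onset to the
#' aligned event (time 0); drop is baseline minus the extremum (in z units,
#' signed positive for the detected direction). When the trace never
#' deviates beyond the threshold the latency is `NA` (flagged) and the drop
#' is still returned.
#'
#' @param object A `psth` object.
#' @param thresh_sd Onset threshold in `sd_ref` units (default 0.05).
#' @param direction `"down"` for calcium troughs, `"up"` for 5-HT rises.
#' @param baseline_window Length-2 numeric, seconds relative to onset.
#' @param sd_ref Reference SD; defaults to the PSTH's stored session SD.
#' @return A one-row tibble: `latency_s`, `drop_z`, `extremum_s`,
#'   `n_events`, `onset_defined`.
#' @export
latency_and_drop <- function(object, thresh_sd = 0.05,
                             direction = c("down", "up"),
                             baseline_window = c(-15, -5), sd_ref = NULL) {
  stopifnot(inherits(object, "psth"))
  direction <- match.arg(direction)
  tt <- object$time
  tr <- object$mean
  if (min(tt) > baseline_window[1] || max(tt) < 0) {
    abort("PSTH window does not cover the baseline window and the onset")
  }
  sd_ref <- sd_ref %||% object$sd_ref

  bl <- mean(tr[tt >= baseline_window[1] & tt <= baseline_window[2]])
  dev <- if (direction == "down") bl - tr else tr - bl

  search <- which(tt >= baseline_window[1])
  k_ext <- search[which.max(dev[search])]
  drop <- dev[k_ext]
  level <- thresh_sd * sd_ref

  if (drop <= level) {
    return(tibble(
      latency_s = NA_real_, drop_z = drop, extremum_s = tt[k_ext],
      n_events = object$n_events, onset_defined = FALSE
    ))
  }

  pre <- which(dev <= level & seq_along(dev) <= k_ext & tt >= baseline_window[1])
  if (!length(pre)) {
    return(tibble(
      latency_s = NA_real_, drop_z = drop, extremum_s = tt[k_ext],
      n_events = object$n_events, onset_defined = FALSE
    ))
  }
  i <- max(pre)
  t_cross <- interp_crossing(tt, dev, i, level)
  tibble(
    latency_s = -t_cross, drop_z = drop, extremum_s = tt[k_ext],
    n_events = object$n_events, onset_defined = TRUE
  )
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf(
    "<psth> %d events, window %.1f..%.1f s at %g Hz\n",
    x$n_events, min(x$time), max(x$time), x$fs
  ))
  invisible(x)
}

#' @export
tidy.psth <- function(x, ...) {
  tibble(time = x$time, mean = x$mean)
}

#' @export
glance.psth <- function(x, ...) {
  tibble(n_events = x$n_events, fs = x$fs, sd_ref = x$sd_ref)
}

#' Plot an event-aligned PSTH
#'
#' @param object A `psth` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psth <- function(object, ...) {
  ggplot2::ggplot(tidy.psth(object), ggplot2::aes(.data$time, .data$mean)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time from event onset (s)", y = "z-scored dF/F",
      subtitle = sprintf("n = %d events", object$n_events)
    ) +
    ggplot2::theme_minimal()
}
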