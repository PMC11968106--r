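# Trough/peak event detection against a 60 s moving baseline, and
# state-transition outcome classification.

#' Moving baseline by 60 s smoothing
#'
#' Centered moving average over `span_s` seconds; the window shrinks at the
#' signal edges.
#'
#' @param x Numeric vector or `t`/`z` tibble (the `z` column is used).
#' @param fs Sampling rate (Hz).
#' @param span_s Smoothing span in seconds (default 60).
#' @return Numeric vector.
#' @export
moving_baseline <- function(x, fs = NULL, span_s = 60) {
  fs <- signal_fs(x, fs)
  v <- if (is.data.frame(x) && "z" %in% names(x)) x$z else pull_signal(x)
  moving_average(v, span_s * fs)
}

#' Detect ISO troughs or phasic peaks against the moving baseline
#'
#' Contiguous NREM segments where the signal deviates from the 60 s moving
#' baseline (computed over NREM-context samples only, so state offsets at
#' epoch boundaries do not bleed into it) by more than `thresh_sd` session SDs — below the baseline for
#' troughs, above for peaks — become events; excursions separated by less
#' than `merge_gap_s` are merged, and each event is located at its extremum
#' sample. Non-NREM samples break excursions. An empty result is valid.
#'
#' @param z A `dff_signal` (typically 1 Hz; the `z` column is used).
#' @param hyp A hypnogram.
#' @param kind `"trough"` or `"peak"`.
#' @param thresh_sd Detection threshold in SD units (default 0.2).
#' @param sd_ref Reference SD; defaults to the session SD of `z` (1 for a
#'   z-scored trace).
#' @param span_s Moving-baseline span (s).
#' @param merge_gap_s Merge sub-threshold gaps shorter than this (s).
#' @param boundary_guard_s Require the event extremum to be surrounded by
#'   NREM context for this many seconds on both sides (default 4):
#'   extrema at the very edge of an epoch are the state transition itself,
#'   not an intra-NREM phasic event.
#' @param min_duration_s Discard merged excursions shorter than this (s):
#'   infraslow events exceed the threshold for several seconds, whereas
#'   single misscored bins at state boundaries produce only 1-2 s spikes.
#' @param include_ma Count MA bins as NREM context (default TRUE: the ISO
#'   spans microarousals).
#' @param fs Sampling rate (Hz).
#' @return An `event_set` tibble: `time`, `magnitude` (|extremum - baseline|
#'   in z units), with attributes `kind`, `thresh_sd`, `sd_ref`.
#' @export
#' @examples
#' s <- simulate_session(session_params("gc", duration_s = 1200), seed = 2)
#' hyp <- truth_hypnogram(s$states, s$params$duration_s)
#' z1 <- downsample_1hz(process_photometry(s$photometry))
#' detect_events(z1, hyp, "trough")
detect_events <- function(z, hyp, kind = c("trough", "peak"), thresh_sd = 0.2,
                          sd_ref = NULL, span_s = 60, merge_gap_s = 10,
                          min_duration_s = 4, boundary_guard_s = 4,
                          include_ma = TRUE, fs = NULL) {
  kind <- match.arg(kind)
  fs <- signal_fs(z, fs)
  zv <- if (is.data.frame(z) && "z" %in% names(z)) z$z else pull_signal(z)
  tv <- if (is.data.frame(z) && "t" %in% names(z)) z$t else (seq_along(zv) - 1) / fs
  sd_ref <- sd_ref %||% sd(zv)

  st <- state_at(hyp, tv)
  in_nrem <- if (include_ma) st %in% c("nrem", "ma") else st == "nrem"
  in_nrem[is.na(in_nrem)] <- FALSE

  # baseline from NREM-context samples only: a plain moving average would
  # bleed the neighbouring state's offset into the first/last half-window of
  # every epoch and manufacture spurious boundary events
  base <- masked_moving_average(zv, in_nrem, span_s * fs)
  dev <- if (kind == "trough") base - zv else zv - base
  dev[!is.finite(dev)] <- -Inf

  above <- dev > thresh_sd * sd_ref & in_nrem
  ev <- tibble(time = numeric(0), magnitude = numeric(0))
  if (any(above)) {
    runs <- index_runs(above)
    runs <- runs[runs$value, c("start", "end")]
    # merge excursions separated by short, fully-NREM gaps
    if (nrow(runs) > 1) {
      merged <- runs[1, ]
      for (i in 2:nrow(runs)) {
        gap_idx <- (merged$end[nrow(merged)] + 1L):(runs$start[i] - 1L)
        gap_s <- (runs$start[i] - merged$end[nrow(merged)] - 1L) / fs
        if (gap_s < merge_gap_s && all(in_nrem[gap_idx])) {
          merged$end[nrow(merged)] <- runs$end[i]
        } else {
          merged <- dplyr::bind_rows(merged, runs[i, ])
        }
      }
      runs <- merged
    }
    runs <- runs[(runs$end - runs$start + 1L) / fs >= min_duration_s, , drop = FALSE]
    if (nrow(runs)) {
      g <- as.integer(round(boundary_guard_s * fs))
      n_s <- length(zv)
      ev <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
        seg <- runs$start[i]:runs$end[i]
        k <- seg[which.max(dev[seg])]
        guard <- max(1L, k - g):min(n_s, k + g)
        if (!all(in_nrem[guard])) {
          return(NULL)
        }
        tibble(time = tv[k], magnitude = dev[k])
      })
      if (!nrow(ev)) {
        ev <- tibble(time = numeric(0), magnitude = numeric(0))
      }
    }
  }

  class(ev) <- c("event_set", class(ev))
  attr(ev, "kind") <- kind
  attr(ev, "thresh_sd") <- thresh_sd
  attr(ev, "sd_ref") <- sd_ref
  ev
}

#' Classify the state-transition outcome of each event
#'
#' Each event is labelled by the first state change within `lookahead_s`
#' after the event time: a microarousal onset gives `"ma"`, a transition to
#' sustained wake gives `"wake"`, a REM onset gives `"rem"`; with no change
#' the label is `"nrem_maintained"`.
#'
#' @param events An `event_set` from [detect_events()].
#' @param hyp A hypnogram with MA intervals.
#' @param lookahead_s Lookahead window (s, default 15).
#' @return The event set with an `outcome` column.
#' @export
classify_outcomes <- function(events, hyp, lookahead_s = 15) {
  bin_s <- attr(hyp, "bin_s") %||% 2
  ma_on <- ma_intervals(hyp)$onset
  # first bin start of each sustained wake / rem bout
  runs <- index_runs(hyp$state)
  bout_start <- hyp$bin_start[runs$start]
  wake_starts <- bout_start[runs$value == "wake"]
  rem_starts <- bout_start[runs$value == "rem"]

  outcome <- vapply(events$time, function(tt) {
    lim <- tt + lookahead_s
    cand_t <- c(
      ma = suppressWarnings(min(ma_on[ma_on > tt & ma_on <= lim])),
      wake = suppressWarnings(min(wake_starts[wake_starts > tt & wake_starts <= lim])),
      rem = suppressWarnings(min(rem_starts[rem_starts > tt & rem_starts <= lim]))
    )
    if (all(!is.finite(cand_t))) {
      return("nrem_maintained")
    }
    names(cand_t)[which.min(cand_t)]
  }, character(1))

  events$outcome <- outcome
  events
}

#' Outcome percentages of an event set
#'
#' @param events An `event_set` with outcomes from [classify_outcomes()].
#' @return A tibble with one row per outcome (`ma`, `nrem_maintained`,
#'   `wake`, `rem`): `n` and `pct`; percentages sum to 100.
#' @export
outcome_percentages <- function(events) {
  if (!"outcome" %in% names(events)) {
    abort("run classify_outcomes() first")
  }
  lv <- c("ma", "nrem_maintained", "wake", "rem")
  n <- vapply(lv, function(o) sum(events$outcome == o), integer(1))
  tibble(outcome = lv, n = n, pct = if (sum(n) > 0) 100 * n / sum(n) else 0 * n)
}

#' @export
tidy.event_set <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.event_set <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    kind = attr(x, "kind") %||% NA_character_,
    thresh_sd = attr(x, "thresh_sd") %||% NA_real_,
    median_magnitude = if (nrow(x)) median(x$magnitude) else NA_real_
  )
}
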