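#' Simulate sleep/wake architecture with microarousals and ISO event schedule
#'
#' Draws a semi-Markov wake/NREM/REM state sequence (exponential dwell times
#' truncated below at per-state minima; wake -> NREM, NREM -> REM with
#' probability `p_rem` else wake, REM -> wake), schedules the NREM-gated
#' infraslow cycles (calcium dips for the `gc`/`mc`/`dual` presets, serotonin
#' pulses for `sert`), and inserts microarousals: a coupled fraction placed a
#' fixed lag after the decline/rise onset of an ISO cycle (realising the
#' programmed trough->MA coupling probability), the remainder uniformly in
#' NREM at a rate that tops the total up to `ma_rate_per_min_nrem`.
#'
#' Every MA lies strictly inside a NREM bout with margins on both sides, has a
#' duration drawn below 15 s, and MAs never overlap. State intervals tile
#' `[0, duration_s]` exactly.
#'
#' @param params An [session_params()] object.
#' @return A list with tibbles `intervals` (`start`, `end`, `state`), `ma`
#'   (`onset`, `duration`, `coupled`), and `cycles` (`onset` = decline/rise
#'   onset, `extremum_time` = programmed trough/peak time, `coupled`), plus
#'   `total_nrem_s`.
#' @export
#' @examples
#' set.seed(1)
#' st <- generate_states(session_params("gc", duration_s = 1200))
#' head(st$intervals)
generate_states <- function(params) {
  p <- params
  if (p$duration_s < 600) {
    abort("duration_s must be at least 600 s to contain a full NREM epoch")
  }

  means <- p$state_dwell_means
  mins <- p$state_dwell_mins

  # semi-Markov chain ------------------------------------------------------
  states <- character(0)
  durs <- numeric(0)
  state <- "wake"
  total <- 0
  while (total < p$duration_s) {
    d <- mins[[state]] + rexp(1, rate = 1 / (means[[state]] - mins[[state]]))
    states <- c(states, state)
    durs <- c(durs, d)
    total <- total + d
    state <- switch(state,
      wake = "nrem",
      nrem = if (runif(1) < p$p_rem) "rem" else "wake",
      rem = "wake"
    )
  }
  ends <- pmin(cumsum(durs), p$duration_s)
  starts <- c(0, head(ends, -1))
  keep <- ends > starts
  intervals <- tibble(start = starts[keep], end = ends[keep], state = states[keep])

  nrem <- dplyr::filter(intervals, .data$state == "nrem")
  if (nrow(nrem) == 0 || max(nrem$end - nrem$start) < mins[["nrem"]]) {
    abort("session too short to contain one full NREM epoch; increase duration_s")
  }
  total_nrem_s <- sum(nrem$end - nrem$start)

  # ISO cycle schedule ------------------------------------------------------
  sert_like <- isTRUE(p$preset == "sert")
  freq_cpm <- if (sert_like) p$sert_peak_freq_cpm else p$iso_freq_cpm
  amp <- p$iso_amp_z
  period <- 60 / freq_cpm
  d_on <- p$iso_decline_s
  d_off <- p$iso_recover_s
  coupling_p <- if (sert_like) p$sert_peak_ma_p else p$trough_ma_coupling_p
  lag <- if (sert_like) p$sert_lead_ma_s else p$trough_to_ma_lag_s

  cycles <- tibble(
    onset = numeric(0), extremum_time = numeric(0),
    epoch_start = numeric(0), epoch_end = numeric(0)
  )
  if (amp > 0) {
    cyc <- purrr::pmap_dfr(
      list(nrem$start, nrem$end),
      function(s0, s1) {
        u <- runif(1, 0, period)
        if (s0 + u > s1) {
          return(NULL)
        }
        onsets <- seq(s0 + u, s1, by = period)
        onsets <- onsets[onsets >= s0 + 2 & onsets + d_on + d_off <= s1]
        if (!length(onsets)) {
          return(NULL)
        }
        tibble(
          onset = onsets, extremum_time = onsets + d_on,
          epoch_start = s0, epoch_end = s1
        )
      }
    )
    if (nrow(cyc)) cycles <- cyc
  }

  # microarousals -----------------------------------------------------------
  ma <- tibble(onset = numeric(0), duration = numeric(0), coupled = logical(0))
  coupled_flag <- logical(nrow(cycles))
  if (nrow(cycles) && coupling_p > 0 && p$ma_rate_per_min_nrem > 0) {
    dur <- runif(nrow(cycles), p$ma_duration_range[1], p$ma_duration_range[2])
    onset <- cycles$onset + lag
    eligible <- onset >= cycles$epoch_start + 4 &
      (onset + dur) <= cycles$epoch_end - 4
    # stratified placement: exactly round(coupling_p * n) cycles couple,
    # drawn among the eligible ones (cycles too close to the epoch end
    # cannot host an MA), so the session-level coupled fraction realizes the
    # programmed probability up to rounding rather than binomial noise
    n_c <- min(round(coupling_p * nrow(cycles)), sum(eligible))
    ok <- rep(FALSE, nrow(cycles))
    if (n_c > 0) {
      ok[sample(which(eligible), n_c)] <- TRUE
    }
    coupled_flag <- ok
    if (any(ok)) {
      ma <- tibble(onset = onset[ok], duration = dur[ok], coupled = TRUE)
    }
  }

  if (p$ma_rate_per_min_nrem > 0) {
    expected_total <- p$ma_rate_per_min_nrem * total_nrem_s / 60
    lambda <- max(0, expected_total - nrow(ma))
    n_unc <- rpois(1, lambda)
    if (n_unc > 0) {
      w <- (nrem$end - nrem$start)
      for (i in seq_len(n_unc)) {
        for (try in 1:50) {
          ep <- sample.int(nrow(nrem), 1, prob = w)
          dur <- runif(1, p$ma_duration_range[1], p$ma_duration_range[2])
          lo <- nrem$start[ep] + 4
          hi <- nrem$end[ep] - 4 - dur
          if (hi <= lo) next
          onset <- runif(1, lo, hi)
          clear <- !nrow(ma) ||
            all(onset > ma$onset + ma$duration + 6 | onset + dur < ma$onset - 6)
          if (clear) {
            ma <- dplyr::bind_rows(
              ma, tibble(onset = onset, duration = dur, coupled = FALSE)
            )
            break
          }
        }
      }
    }
  }
  ma <- dplyr::arrange(ma, .data$onset)

  cycles_out <- tibble(
    onset = cycles$onset,
    extremum_time = cycles$extremum_time,
    coupled = coupled_flag
  )

  list(
    intervals = intervals,
    ma = ma,
    cycles = cycles_out,
    total_nrem_s = total_nrem_s
  )
}

# Per-sample state codes over [0, duration): 1 wake, 2 nrem, 3 rem, 4 ma.
state_codes <- function(states, n, fs) {
  code <- integer(n)
  iv <- states$intervals
  lev <- c(wake = 1L, nrem = 2L, rem = 3L)
  for (i in seq_len(nrow(iv))) {
    a <- max(1L, floor(iv$start[i] * fs) + 1L)
    b <- min(n, ceiling(iv$end[i] * fs))
    if (b >= a) code[a:b] <- lev[[iv$state[i]]]
  }
  if (nrow(states$ma)) {
    for (i in seq_len(nrow(states$ma))) {
      a <- max(1L, floor(states$ma$onset[i] * fs) + 1L)
      b <- min(n, ceiling((states$ma$onset[i] + states$ma$duration[i]) * fs))
      if (b >= a) code[a:b] <- 4L
    }
  }
  code[code == 0L] <- 1L
  code
}

# True hypnogram on a 2 s bin grid, for agreement checks against scoring.
#' Ground-truth hypnogram of a simulated session
#'
#' Bins the generator's state intervals and microarousals onto the scoring
#' grid, producing the same structure as [score_states()] so that recovery
#' tests can compare per-bin labels directly.
#'
#' @param states The `states` element of a simulated session (or the result
#'   of [generate_states()]).
#' @param duration_s Session length in seconds.
#' @param bin_s Bin width in seconds (default 2).
#' @return A `hypnogram` tibble (see [score_states()]).
#' @export
truth_hypnogram <- function(states, duration_s, bin_s = 2) {
  n_bins <- floor(duration_s / bin_s)
  centers <- (seq_len(n_bins) - 0.5) * bin_s
  fs_grid <- 50
  code <- state_codes(states, as.integer(duration_s * fs_grid), fs_grid)
  idx <- pmin(length(code), pmax(1L, round(centers * fs_grid)))
  labels <- c("wake", "nrem", "rem", "ma")[code[idx]]
  ma_iv <- tibble(
    start = states$ma$onset,
    end = states$ma$onset + states$ma$duration,
    onset = states$ma$onset
  )
  new_hypnogram(
    bin_start = (seq_len(n_bins) - 1L) * bin_s,
    state = labels, bin_s = bin_s, ma_intervals = ma_iv
  )
}
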