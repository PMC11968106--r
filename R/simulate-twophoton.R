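#' Simulate a two-photon cell population with programmed NREM modulation
#'
#' Each cell emits calcium transients (instantaneous rise, exponential decay,
#' GCaMP6s-like tau 1.5 s) from an inhomogeneous Poisson process whose rate is
#' scaled in NREM versus quiet wake: up-regulated cells by `up_gain`,
#' down-regulated cells by `down_gain`, non-significant cells unchanged.
#' Up-regulated cells are silenced during microarousal bouts. Locomotion
#' bouts inside wake double as the motion mask: velocity is strictly positive
#' only there, and all cells get a mild locomotion gain. The neuropil channel
#' is a shared slow background; the raw channel is cell baseline + transients
#' + neuropil + sensor noise, so `raw - neuropil` isolates the somatic trace.
#'
#' Cell labels are assigned deterministically so the programmed fractions are
#' exact: the first `round(frac_up * n)` cells are up, the next
#' `round(frac_down * n)` down, the rest ns.
#'
#' @param params An [session_params()] object.
#' @param states Result of [generate_states()].
#' @param n_cells Number of cells (>= 10); defaults to `params$n_cells`.
#' @return A list: `cells` long tibble (`cell_id`, `t`, `raw`, `neuropil`),
#'   `velocity` tibble (`t`, `value`), `labels` tibble (`cell_id`, `label`).
#' @export
generate_twophoton <- function(params, states, n_cells = params$n_cells) {
  p <- params
  if (n_cells < 10) {
    abort("n_cells must be at least 10")
  }
  fs <- p$fs_2p
  n <- as.integer(round(p$duration_s * fs))
  code <- state_codes(states, n, fs)

  # locomotion bouts inside wake intervals --------------------------------
  run_mask <- logical(n)
  vel <- numeric(n)
  wake_iv <- dplyr::filter(states$intervals, .data$state == "wake")
  for (i in seq_len(nrow(wake_iv))) {
    t0 <- wake_iv$start[i]
    t1 <- wake_iv$end[i]
    pos <- t0 + runif(1, 2, 8)
    while (pos < t1 - 4) {
      len <- runif(1, 5, 25)
      b0 <- pos
      b1 <- min(pos + len, t1 - 1)
      a <- floor(b0 * fs) + 1L
      b <- min(n, floor(b1 * fs))
      if (b >= a && runif(1) < p$motion_frac / 0.5) {
        run_mask[a:b] <- TRUE
        vel[a:b] <- runif(1, 5, 15)
      }
      pos <- b1 + runif(1, 5, 30)
    }
  }

  n_up <- round(p$frac_up * n_cells)
  n_down <- round(p$frac_down * n_cells)
  labels <- rep(c("up", "down", "ns"), c(n_up, n_down, n_cells - n_up - n_down))
  cell_ids <- sprintf("cell_%03d", seq_len(n_cells))

  neuropil_common <- 20 + 3 * ou_noise(n, fs, 30, 1)
  decay <- exp(-1 / (fs * p$transient_tau_s))
  t_grid <- (seq_len(n) - 1L) / fs

  is_nrem <- code == 2L
  is_ma <- code == 4L

  traces <- purrr::map(seq_len(n_cells), function(ci) {
    lab <- labels[ci]
    gain <- rep(1, n)
    gain[is_nrem] <- switch(lab, up = p$up_gain, down = p$down_gain, ns = 1)
    if (lab == "up") gain[is_ma] <- 0
    gain[run_mask] <- gain[run_mask] * p$run_gain
    rate <- p$cell_rate_hz * gain
    counts <- rpois(n, rate / fs)
    amp <- p$transient_amp * runif(1, 0.8, 1.2)
    transients <- as.numeric(
      stats::filter(counts * amp, decay, method = "recursive")
    )
    base <- runif(1, 25, 35)
    neuropil <- neuropil_common + rnorm(n, sd = 0.5)
    raw <- base + transients + neuropil + rnorm(n, sd = 2)
    tibble(cell_id = cell_ids[ci], t = t_grid, raw = raw, neuropil = neuropil)
  })
  cells <- dplyr::bind_rows(traces)
  attr(cells, "fs") <- fs

  list(
    cells = cells,
    velocity = new_signal_tbl(vel, fs),
    labels = tibble(cell_id = cell_ids, label = labels)
  )
}
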