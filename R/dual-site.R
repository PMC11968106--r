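# State-resolved correlation between two simultaneously recorded sites.

#' Align two processed signals on a common 1 Hz grid
#'
#' Both signals are linearly interpolated onto a shared 1 Hz grid covering
#' their temporal overlap.
#'
#' @param sig_a,sig_b `dff_signal` tibbles (columns `t` and `z`).
#' @param min_overlap_s Minimum overlap required (s, default 120).
#' @return A tibble `t`, `a`, `b` at 1 Hz.
#' @export
align_signals <- function(sig_a, sig_b, min_overlap_s = 120) {
  ta <- sig_a$t
  tb <- sig_b$t
  start <- max(min(ta), min(tb))
  end <- min(max(ta), max(tb))
  if (!is.finite(start) || !is.finite(end) || end - start < min_overlap_s) {
    abort(sprintf(
      "signals overlap for %.1f s; at least %.0f s are required",
      max(0, end - start), min_overlap_s
    ))
  }
  grid <- seq(ceiling(start * 2) / 2, end, by = 1)
  tibble(
    t = grid,
    a = approx(ta, pull_signal(sig_a, "z"), xout = grid)$y,
    b = approx(tb, pull_signal(sig_b, "z"), xout = grid)$y
  )
}

#' Pearson correlation between two sites, per brain state
#'
#' The correlation is computed over the pooled 1 Hz bins of each state
#' within the session. MA bins are excluded from NREM by default,
#' consistent with the scoring module's convention. States with fewer than
#' `min_bins` bins are reported with a `low_n` flag; absent states give
#' `NA`.
#'
#' @param paired Output of [align_signals()].
#' @param hyp A hypnogram covering the overlap.
#' @param include_ma Count MA bins as NREM.
#' @param min_bins Minimum bins for a reliable estimate (default 30).
#' @param per_epoch Compute r per contiguous state bout and average (useful
#'   for inspecting bout-to-bout variability, e.g. in REM); default FALSE:
#'   pooled bins per session.
#' @return A `state_correlation` tibble: `state`, `r`, `n_bins`, `low_n`
#'   (and `n_epochs`, `r_sd` when `per_epoch`).
#' @export
state_correlation <- function(paired, hyp, include_ma = FALSE, min_bins = 30,
                              per_epoch = FALSE) {
  st <- state_at(hyp, paired$t)
  pick <- function(target) {
    if (target == "nrem" && include_ma) st %in% c("nrem", "ma") else st == target
  }
  out <- purrr::map_dfr(c("wake", "nrem", "rem"), function(target) {
    sel <- pick(target) & !is.na(st) &
      is.finite(paired$a) & is.finite(paired$b)
    n <- sum(sel)
    if (per_epoch) {
      runs <- index_runs(sel)
      runs <- runs[runs$value & (runs$end - runs$start + 1L) >= 10, , drop = FALSE]
      rs <- vapply(seq_len(nrow(runs)), function(i) {
        j <- runs$start[i]:runs$end[i]
        cor(paired$a[j], paired$b[j])
      }, numeric(1))
      rs <- rs[is.finite(rs)]
      return(tibble(
        state = target, r = if (length(rs)) mean(rs) else NA_real_,
        n_bins = n, low_n = n < min_bins,
        n_epochs = length(rs),
        r_sd = if (length(rs) > 1) stats::sd(rs) else NA_real_
      ))
    }
    r <- if (n >= 3) cor(paired$a[sel], paired$b[sel]) else NA_real_
    tibble(state = target, r = r, n_bins = n, low_n = n < min_bins)
  })
  class(out) <- c("state_correlation", class(out))
  out
}

#' @export
tidy.state_correlation <- function(x, ...) {
  as_tibble(x)
}

#' Plot per-state dual-site correlations
#'
#' @param object A `state_correlation` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.state_correlation <- function(object, ...) {
  df <- as_tibble(object)
  df$state <- factor(df$state, levels = c("wake", "nrem", "rem"))
  ggplot2::ggplot(df, ggplot2::aes(.data$state, .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_col(width = 0.6, fill = "steelblue") +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = NULL, y = "Pearson r") +
    ggplot2::theme_minimal()
}
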