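# Two-photon single-cell dF/F with minimax partial baselines, NREM
# up/down classification, and MA-aligned population averages.

#' Per-cell dF/F with minimax-filtered partial baselines
#'
#' The unfiltered neuropil is subtracted from the unfiltered raw trace; two
#' partial baselines are then estimated by minimax-filtering (rolling
#' minimum followed by rolling maximum, i.e. a morphological opening) the
#' smoothed residual and the smoothed neuropil. dF/F is
#' `(residual - B_res) / (B_res + B_np)`.
#'
#' @param raw,neuropil Numeric vectors of equal length (raw fluorescence and
#'   matched neuropil).
#' @param fs Sampling rate (Hz, default 10).
#' @param window_s Minimax window (s, default 60).
#' @param smooth_s Pre-smoothing moving-average span (s, default 5).
#' @param np_coef Neuropil subtraction coefficient (default 1: unscaled).
#' @return A tibble: `t`, `dff`.
#' @export
neuropil_dff <- function(raw, neuropil, fs = 10, window_s = 60, smooth_s = 5,
                         np_coef = 1) {
  if (length(raw) != length(neuropil)) {
    abort("raw and neuropil must have equal length")
  }
  n_w <- as.integer(round(window_s * fs))
  if (length(raw) < n_w) {
    abort("trace shorter than the baseline window")
  }
  residual <- raw - np_coef * neuropil
  b_res <- minimax_baseline(moving_average(residual, smooth_s * fs), n_w)
  b_np <- minimax_baseline(moving_average(neuropil, smooth_s * fs), n_w)
  denom <- b_res + b_np
  bad <- which(denom <= 0)
  if (length(bad)) {
    abort(sprintf(
      "sum of partial baselines is non-positive at sample %d; dF/F undefined",
      bad[1]
    ))
  }
  out <- tibble(t = (seq_along(raw) - 1L) / fs, dff = (residual - b_res) / denom)
  attr(out, "fs") <- fs
  out
}

# dF/F for every cell of a long (cell_id, t, raw, neuropil) table.
#' Compute dF/F for a population of cells
#'
#' Applies [neuropil_dff()] to each cell of a long trace table.
#'
#' @param cells Tibble with columns `cell_id`, `t`, `raw`, `neuropil`.
#' @param fs Sampling rate (Hz).
#' @param ... Passed to [neuropil_dff()].
#' @return The input with a `dff` column added.
#' @export
cells_dff <- function(cells, fs = NULL, ...) {
  fs <- signal_fs(cells, fs) # t repeats per cell; attribute preferred
  cells |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      df$dff <- neuropil_dff(df$raw, df$neuropil, fs = fs, ...)$dff
      df
    }) |>
    dplyr::ungroup()
}

# Per-state analysis bins: disjoint `bin_s` windows fully inside one state,
# with quiet wake requiring velocity below the motion threshold throughout.
analysis_bins <- function(hyp, velocity, fs_vel, duration_s, bin_s = 5,
                          motion_thresh = 0.5) {
  n_bins <- floor(duration_s / bin_s)
  starts <- (seq_len(n_bins) - 1L) * bin_s
  vel <- pull_signal(velocity)
  bin_state <- vapply(starts, function(s) {
    st <- unique(state_at(hyp, c(s + 0.25, s + bin_s / 2, s + bin_s - 0.25)))
    if (length(st) != 1L || is.na(st)) {
      return(NA_character_)
    }
    st
  }, character(1))
  vmax <- vapply(starts, function(s) {
    a <- floor(s * fs_vel) + 1L
    b <- min(length(vel), ceiling((s + bin_s) * fs_vel))
    if (b < a) {
      return(NA_real_)
    }
    max(vel[a:b])
  }, numeric(1))
  cls <- dplyr::case_when(
    bin_state == "nrem" ~ "nrem",
    bin_state == "wake" & vmax < motion_thresh ~ "quiet_wake",
    TRUE ~ NA_character_
  )
  tibble(start = starts, end = starts + bin_s, class = cls)
}

#' Classify cells as NREM up-regulated, down-regulated, or non-significant
#'
#' Per cell, mean dF/F is computed in disjoint `bin_s` bins lying fully in
#' NREM or in quiet wake (wake with velocity below `motion_thresh`
#' throughout the bin; MA bins are excluded from NREM), and the two sets of
#' bin means are compared with Welch's unpaired t-test. A cell is `up` when
#' p < alpha and the NREM mean exceeds the quiet-wake mean, `down` for the
#' opposite direction, otherwise `ns`.
#'
#' @param cells Long tibble (`cell_id`, `t`, `raw`, `neuropil`), or the
#'   output of [cells_dff()] (with `dff`).
#' @param hyp A hypnogram.
#' @param velocity Treadmill velocity (`t`/`value` tibble or vector).
#' @param fs Trace sampling rate (Hz).
#' @param fs_vel Velocity sampling rate (Hz); defaults to `fs`.
#' @param alpha Significance level (default 0.05, no multiplicity
#'   correction — per-cell classification).
#' @param bin_s Analysis bin (s, default 5; longer than the sensor decay so
#'   bin means are effectively independent).
#' @param motion_thresh Velocity threshold for quiet wake (cm/s).
#' @return A `cell_classification` tibble: `cell_id`, `mean_quiet_wake`,
#'   `mean_nrem`, `p_value`, `label`; per-label fractions are in the
#'   `fractions` attribute.
#' @export
classify_cells <- function(cells, hyp, velocity, fs = NULL, fs_vel = NULL,
                           alpha = 0.05, bin_s = 5, motion_thresh = 0.5) {
  fs <- signal_fs(cells, fs)
  fs_vel <- fs_vel %||% signal_fs(velocity, fs)
  if (!"dff" %in% names(cells)) {
    cells <- cells_dff(cells, fs)
  }
  duration_s <- max(cells$t) + 1 / fs
  bins <- analysis_bins(hyp, velocity, fs_vel, duration_s, bin_s, motion_thresh)
  bins <- dplyr::filter(bins, !is.na(.data$class))
  n_qw <- sum(bins$class == "quiet_wake") * bin_s
  n_nr <- sum(bins$class == "nrem") * bin_s
  if (n_qw < 30 || n_nr < 30) {
    abort(sprintf(
      "need at least 30 s of both quiet wake and NREM (have %.0f / %.0f s)",
      n_qw, n_nr
    ))
  }

  spb <- as.integer(round(bin_s * fs))
  bin_idx0 <- as.integer(round(bins$start * fs))

  out <- cells |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(function(df, key) {
      means <- vapply(bin_idx0, function(i0) {
        mean(df$dff[(i0 + 1L):min(nrow(df), i0 + spb)])
      }, numeric(1))
      qw <- means[bins$class == "quiet_wake"]
      nr <- means[bins$class == "nrem"]
      tt <- t.test(nr, qw)
      tibble(
        mean_quiet_wake = mean(qw), mean_nrem = mean(nr),
        p_value = tt$p.value
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      label = dplyr::case_when(
        .data$p_value < alpha & .data$mean_nrem > .data$mean_quiet_wake ~ "up",
        .data$p_value < alpha & .data$mean_nrem < .data$mean_quiet_wake ~ "down",
        TRUE ~ "ns"
      )
    )
  class(out) <- c("cell_classification", class(out))
  attr(out, "fractions") <- c(
    up = mean(out$label == "up"),
    down = mean(out$label == "down"),
    ns = mean(out$label == "ns")
  )
  attr(out, "alpha") <- alpha
  out
}

#' Fractions of up/down/ns cells
#'
#' @param x A `cell_classification` from [classify_cells()].
#' @param ... Unused.
#' @return A one-row tibble: `frac_up`, `frac_down`, `frac_ns`, `n_cells`.
#' @export
glance.cell_classification <- function(x, ...) {
  f <- attr(x, "fractions")
  tibble(
    frac_up = f[["up"]], frac_down = f[["down"]], frac_ns = f[["ns"]],
    n_cells = nrow(x)
  )
}

#' Microarousal-aligned activity by cell class
#'
#' Class-averaged dF/F aligned to MA onsets, plus a per-class paired
#' comparison of each cell's mean dF/F inside MA windows versus flanking
#' NREM (the 10 to 2 s preceding each MA onset).
#'
#' @param cells Long tibble with `dff` (see [cells_dff()]).
#' @param labels Tibble `cell_id`, `label` (from [classify_cells()] or
#'   ground truth).
#' @param hyp A hypnogram with MA intervals.
#' @param fs Sampling rate (Hz).
#' @param pre_s,post_s Aligned-trace window (s).
#' @return A list: `traces` (tibble `label`, `time`, `mean`), `tests`
#'   (tibble `label`, `mean_nrem`, `mean_ma`, `p_value`, `n_cells`). With
#'   zero MAs both are empty tibbles (flagged by attribute `n_ma = 0`).
#' @export
ma_aligned_activity <- function(cells, labels, hyp, fs = NULL,
                                pre_s = 10, post_s = 15) {
  fs <- signal_fs(cells, fs)
  iv <- ma_intervals(hyp)
  if (!nrow(iv)) {
    out <- list(
      traces = tibble(label = character(0), time = numeric(0), mean = numeric(0)),
      tests = tibble(
        label = character(0), mean_nrem = numeric(0), mean_ma = numeric(0),
        p_value = numeric(0), n_cells = integer(0)
      )
    )
    attr(out, "n_ma") <- 0L
    return(out)
  }
  if (!"dff" %in% names(cells)) {
    cells <- cells_dff(cells, fs)
  }
  cells <- dplyr::left_join(cells, labels, by = "cell_id")

  k_pre <- as.integer(round(pre_s * fs))
  k_post <- as.integer(round(post_s * fs))
  rel <- (-k_pre):k_post

  per_cell <- cells |>
    dplyr::group_by(.data$cell_id, .data$label) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      idx0 <- round(iv$onset * fs) + 1L
      ok <- idx0 - k_pre >= 1L & idx0 + k_post <= n
      snip <- rowMeans(vapply(
        idx0[ok], function(i) df$dff[i + rel], numeric(length(rel))
      ))
      ma_mean <- mean(unlist(purrr::map2(iv$onset, iv$end, function(a, b) {
        df$dff[max(1L, floor(a * fs) + 1L):min(n, ceiling(b * fs))]
      })))
      pre_mean <- mean(unlist(purrr::map(iv$onset, function(a) {
        df$dff[max(1L, floor((a - 10) * fs) + 1L):max(1L, ceiling((a - 2) * fs))]
      })))
      tibble(
        time = list(rel / fs), trace = list(snip),
        mean_ma = ma_mean, mean_nrem = pre_mean
      )
    }) |>
    dplyr::ungroup()

  traces <- per_cell |>
    tidyr::unnest(c("time", "trace")) |>
    dplyr::group_by(.data$label, .data$time) |>
    dplyr::summarise(mean = mean(.data$trace), .groups = "drop")

  tests <- per_cell |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      p_value = tryCatch(
        t.test(.data$mean_ma, .data$mean_nrem, paired = TRUE)$p.value,
        error = function(e) NA_real_
      ),
      mean_nrem = mean(.data$mean_nrem),
      mean_ma = mean(.data$mean_ma),
      n_cells = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select("label", "mean_nrem", "mean_ma", "p_value", "n_cells")

  out <- list(traces = traces, tests = tests)
  attr(out, "n_ma") <- nrow(iv)
  out
}

#' Plot classified cell fractions
#'
#' @param object A `cell_classification` from [classify_cells()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cell_classification <- function(object, ...) {
  f <- attr(object, "fractions")
  df <- tibble(
    label = factor(names(f), levels = c("up", "down", "ns")),
    fraction = as.numeric(f)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$label, .data$fraction, fill = .data$label)) +
    ggplot2::geom_col(width = 0.7, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(up = "firebrick", down = "steelblue", ns = "grey60")) +
    ggplot2::labs(x = NULL, y = "fraction of cells") +
    ggplot2::theme_minimal()
}
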