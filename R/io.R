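# Session I/O: delimited-table readers/writers, manifest handling, and the
# pipeline orchestrator. All interval tables are half-open [start, end) in
# seconds from session start.

#' Write a hypnogram as an interval TSV
#'
#' Columns `start_s`, `end_s`, `label`; contiguous bins with the same label
#' are collapsed into one interval. Microarousal onsets are preserved in an
#' `onset_s` column (NA for non-MA rows).
#'
#' @param hyp A hypnogram.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  runs <- index_runs(hyp$state)
  iv <- ma_intervals(hyp)
  df <- tibble(
    start_s = hyp$bin_start[runs$start],
    end_s = hyp$bin_end[runs$end],
    label = runs$value
  )
  df$onset_s <- NA_real_
  if (nrow(iv)) {
    for (i in which(df$label == "ma")) {
      hit <- which(iv$onset >= df$start_s[i] & iv$onset < df$end_s[i])
      if (length(hit)) df$onset_s[i] <- iv$onset[hit[1]]
    }
  }
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read an interval-TSV hypnogram
#'
#' @param path File written by [write_hypnogram()] (or any TSV with
#'   `start_s`, `end_s`, `label`).
#' @param bin_s Bin width of the reconstructed hypnogram (s).
#' @return A `hypnogram` tibble.
#' @export
read_hypnogram <- function(path, bin_s = 2) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("start_s", "end_s", "label")
  if (!all(need %in% names(df))) {
    abort("hypnogram TSV needs columns start_s, end_s, label")
  }
  dur <- max(df$end_s)
  n_bins <- as.integer(round(dur / bin_s))
  state <- rep("wake", n_bins)
  centers <- (seq_len(n_bins) - 0.5) * bin_s
  for (i in seq_len(nrow(df))) {
    state[centers >= df$start_s[i] & centers < df$end_s[i]] <- df$label[i]
  }
  ma_rows <- df[df$label == "ma", , drop = FALSE]
  iv <- tibble(
    start = ma_rows$start_s, end = ma_rows$end_s,
    onset = if ("onset_s" %in% names(ma_rows)) {
      ifelse(is.na(ma_rows$onset_s), ma_rows$start_s, ma_rows$onset_s)
    } else {
      ma_rows$start_s
    }
  )
  new_hypnogram((seq_len(n_bins) - 1L) * bin_s, state, bin_s, ma_intervals = iv)
}

#' Write a simulated session to a directory of delimited tables
#'
#' Emits `eeg.tsv`/`emg.tsv` (`t`, `value`), `photometry.tsv` (`t`, `f465`,
#' `f405`; plus `photometry_b.tsv` for dual-site sessions), `cells.tsv` and
#' `velocity.tsv` for two-photon sessions, `hypnogram_true.tsv`,
#' `ground_truth.json` (parameters, MA onsets, cycle schedule, cell labels)
#' and `manifest.json` listing the files with their sampling rates.
#'
#' @param session An `iso_session`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "iso_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- session$params
  manifest <- list(
    preset = p$preset, seed = session$seed, duration_s = p$duration_s,
    files = list()
  )
  add <- function(manifest, name, fname, fs) {
    manifest$files[[name]] <- list(path = fname, fs = fs)
    manifest
  }

  readr::write_tsv(session$eeg, file.path(dir, "eeg.tsv"))
  manifest <- add(manifest, "eeg", "eeg.tsv", p$fs_eeg)
  readr::write_tsv(session$emg, file.path(dir, "emg.tsv"))
  manifest <- add(manifest, "emg", "emg.tsv", p$fs_eeg)
  if (!is.null(session$photometry)) {
    readr::write_tsv(session$photometry, file.path(dir, "photometry.tsv"))
    manifest <- add(manifest, "photometry", "photometry.tsv", p$fs_photo)
  }
  if (!is.null(session$photometry_b)) {
    readr::write_tsv(session$photometry_b, file.path(dir, "photometry_b.tsv"))
    manifest <- add(manifest, "photometry_b", "photometry_b.tsv", p$fs_photo)
  }
  if (!is.null(session$cells)) {
    readr::write_tsv(session$cells, file.path(dir, "cells.tsv"))
    manifest <- add(manifest, "cells", "cells.tsv", p$fs_2p)
    readr::write_tsv(session$velocity, file.path(dir, "velocity.tsv"))
    manifest <- add(manifest, "velocity", "velocity.tsv", p$fs_2p)
  }

  truth <- session$states
  write_hypnogram(
    truth_hypnogram(truth, p$duration_s),
    file.path(dir, "hypnogram_true.tsv")
  )
  manifest$files[["hypnogram"]] <- list(path = "hypnogram_true.tsv", fs = NA)

  gt <- list(
    params = unclass(p),
    state_intervals = truth$intervals,
    ma = truth$ma,
    cycles = truth$cycles
  )
  if (!is.null(session$cell_labels)) gt$cell_labels <- session$cell_labels
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(file.path(dir, "manifest.json"))
}

#' Read a session bundle from a manifest
#'
#' Validates that every referenced file exists and parses, that sampling
#' rates are positive, and that at least EEG+EMG or a precomputed hypnogram
#' is present.
#'
#' @param manifest Path to a `manifest.json` written by [write_session()]
#'   (or hand-written with the same structure).
#' @return A list of class `session_bundle`: loaded tibbles plus `fs` values
#'   and the manifest metadata.
#' @export
read_session <- function(manifest) {
  if (!file.exists(manifest)) {
    abort(sprintf("manifest not found: %s", manifest))
  }
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  has <- function(nm) !is.null(m$files[[nm]])
  if (!((has("eeg") && has("emg")) || has("hypnogram"))) {
    abort("manifest must list either eeg+emg or a precomputed hypnogram")
  }
  bundle <- list(
    preset = m$preset %||% NA_character_,
    seed = m$seed %||% NA_integer_,
    duration_s = m$duration_s %||% NA_real_
  )
  for (nm in names(m$files)) {
    f <- m$files[[nm]]
    path <- file.path(dir, f$path)
    if (!file.exists(path)) {
      abort(sprintf("file listed in manifest is missing: %s", path))
    }
    if (nm == "hypnogram") {
      bundle$hypnogram <- read_hypnogram(path)
      next
    }
    tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    fs <- f$fs
    if (!is.null(fs) && (!is.numeric(fs) || fs <= 0)) {
      abort(sprintf("invalid sampling rate for '%s'", nm))
    }
    attr(tb, "fs") <- fs
    bundle[[nm]] <- tb
  }
  structure(bundle, class = "session_bundle")
}

#' Run an analysis track end to end
#'
#' Chains the pipeline stages in recording order for one of the three
#' tracks:
#' * `"photometry"` — score states and MAs, preprocess photometry, downsample
#'   to 1 Hz, infraslow spectra by state, trough/peak detection with outcome
#'   classification, MA-aligned PSTH with latency and drop.
#' * `"dual_site"` — as above for site A, plus alignment with site B and
#'   per-state Pearson correlation.
#' * `"twophoton"` — score states, per-cell dF/F, up/down classification,
#'   MA-aligned class averages.
#'
#' With `out_dir` set, every numeric result is written as TSV/JSON together
#' with a `run_log.json` capturing the configuration; rerunning with the
#' same inputs and config is byte-identical.
#'
#' @param x An `iso_session` (from [simulate_session()]) or a
#'   `session_bundle` (from [read_session()]).
#' @param track `"photometry"`, `"dual_site"`, or `"twophoton"`.
#' @param out_dir Optional output directory.
#' @param event_kind `"trough"` or `"peak"`; default `"peak"` for the sert
#'   preset, `"trough"` otherwise.
#' @param config Named list of overrides: `emg_thresh`, `td_thresh`,
#'   `thresh_sd`, `lookahead_s`, `alpha`, `psth_direction`.
#' @return A list of stage results (class `iso_results`); see Details.
#' @export
run_pipeline <- function(x, track = c("photometry", "dual_site", "twophoton"),
                         out_dir = NULL, event_kind = NULL, config = list()) {
  track <- match.arg(track)
  cfg <- utils::modifyList(
    list(
      emg_thresh = NULL, td_thresh = 1.5, thresh_sd = 0.2,
      lookahead_s = 15, alpha = 0.05, psth_direction = NULL
    ),
    config
  )
  preset <- if (inherits(x, "iso_session")) x$params$preset else x$preset
  event_kind <- event_kind %||%
    (if (identical(preset, "sert")) "peak" else "trough")
  direction <- cfg$psth_direction %||%
    (if (event_kind == "peak") "up" else "down")

  fs_sig <- function(nm) {
    if (inherits(x, "iso_session")) {
      switch(nm,
        eeg = , emg = x$params$fs_eeg,
        photometry = , photometry_b = x$params$fs_photo,
        cells = , velocity = x$params$fs_2p
      )
    } else {
      attr(x[[nm]], "fs") %||% signal_fs(x[[nm]])
    }
  }

  need <- function(nm) {
    if (is.null(x[[nm]])) {
      abort(sprintf("track '%s' requires component '%s'", track, nm))
    }
    x[[nm]]
  }

  res <- list(track = track, config = cfg)

  hyp <- if (!inherits(x, "iso_session") && !is.null(x$hypnogram)) {
    x$hypnogram
  } else {
    score_states(
      need("eeg"), need("emg"),
      fs_eeg = fs_sig("eeg"), fs_emg = fs_sig("emg"),
      emg_thresh = cfg$emg_thresh, td_thresh = cfg$td_thresh
    )
  }
  res$hypnogram <- hyp
  res$state_durations <- state_durations(hyp)

  if (track %in% c("photometry", "dual_site")) {
    proc <- process_photometry(need("photometry"), fs = fs_sig("photometry"))
    z1 <- downsample_1hz(proc)
    res$dff <- proc
    res$z1hz <- z1
    spec <- iso_spectrogram(z1)
    res$iso_power <- state_iso_power(spec, hyp)
    ev <- detect_events(z1, hyp, kind = event_kind, thresh_sd = cfg$thresh_sd)
    ev <- classify_outcomes(ev, hyp, lookahead_s = cfg$lookahead_s)
    res$events <- ev
    res$outcomes <- outcome_percentages(ev)
    on <- ma_intervals(hyp)$onset
    if (length(on)) {
      ps <- psth(proc, on)
      res$psth <- ps
      res$latency <- latency_and_drop(ps, direction = direction)
    }
  }

  if (track == "dual_site") {
    proc_b <- process_photometry(need("photometry_b"), fs = fs_sig("photometry_b"))
    paired <- align_signals(downsample_1hz(res$dff), downsample_1hz(proc_b))
    res$dff_b <- proc_b
    res$correlation <- state_correlation(paired, hyp)
  }

  if (track == "twophoton") {
    cells <- need("cells")
    attr(cells, "fs") <- fs_sig("cells")
    cells <- cells_dff(cells, fs = fs_sig("cells"))
    cls <- classify_cells(cells, hyp, need("velocity"),
      fs = fs_sig("cells"), fs_vel = fs_sig("velocity"), alpha = cfg$alpha
    )
    res$cells <- cls
    res$fractions <- glance.cell_classification(cls)
    res$ma_activity <- ma_aligned_activity(
      cells, dplyr::select(cls, "cell_id", "label"), hyp,
      fs = fs_sig("cells")
    )
  }

  class(res) <- "iso_results"
  if (!is.null(out_dir)) {
    write_results(res, out_dir)
  }
  res
}

write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_hypnogram(res$hypnogram, file.path(out_dir, "hypnogram.tsv"))
  readr::write_tsv(res$state_durations, file.path(out_dir, "state_durations.tsv"))
  if (!is.null(res$z1hz)) {
    readr::write_tsv(res$z1hz, file.path(out_dir, "dff_1hz.tsv"))
  }
  if (!is.null(res$iso_power)) {
    readr::write_tsv(res$iso_power, file.path(out_dir, "iso_power.tsv"))
  }
  if (!is.null(res$events)) {
    readr::write_tsv(as_tibble(res$events), file.path(out_dir, "events.tsv"))
    readr::write_tsv(res$outcomes, file.path(out_dir, "outcomes.tsv"))
  }
  if (!is.null(res$psth)) {
    readr::write_tsv(tidy.psth(res$psth), file.path(out_dir, "psth.tsv"))
  }
  summary <- list(track = res$track, config = res$config)
  if (!is.null(res$latency)) summary$latency <- as.list(res$latency)
  if (!is.null(res$correlation)) {
    readr::write_tsv(as_tibble(res$correlation), file.path(out_dir, "correlation.tsv"))
  }
  if (!is.null(res$cells)) {
    readr::write_tsv(as_tibble(res$cells), file.path(out_dir, "cell_classification.tsv"))
    summary$fractions <- as.list(res$fractions)
  }
  jsonlite::write_json(
    summary, file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
  )
  invisible(out_dir)
}

#' @export
print.iso_results <- function(x, ...) {
  cat(sprintf("<iso_results> track '%s'\n", x$track))
  if (!is.null(x$outcomes)) {
    cat("  outcomes (%):\n")
    print(x$outcomes)
  }
  if (!is.null(x$latency)) {
    cat(sprintf(
      "  latency %.2f s, drop %.2f z (%d events)\n",
      x$latency$latency_s, x$latency$drop_z, x$latency$n_events
    ))
  }
  if (!is.null(x$fractions)) {
    print(x$fractions)
  }
  invisible(x)
}
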