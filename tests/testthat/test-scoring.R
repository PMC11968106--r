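# Sleep scoring and microarousal detection.

test_that("an all-wake session scores 100% wake", {
  p <- short_params("gc", 600)
  st <- list(
    intervals = tibble::tibble(start = 0, end = 600, state = "wake"),
    ma = tibble::tibble(onset = numeric(0), duration = numeric(0), coupled = logical(0)),
    cycles = tibble::tibble(onset = numeric(0), extremum_time = numeric(0), coupled = logical(0))
  )
  sig <- withr::with_seed(1, generate_eeg_emg(p, st))
  # degenerate unimodal EMG: supply an explicit threshold below wake RMS
  hyp <- score_states(sig$eeg, sig$emg,
    fs_eeg = p$fs_eeg, fs_emg = p$fs_eeg, emg_thresh = 10
  )
  expect_true(all(hyp$state == "wake"))
})

test_that("scoring is deterministic and idempotent given thresholds", {
  fx <- gc_fixture()
  s <- fx$session
  h1 <- score_states(s$eeg, s$emg)
  h2 <- score_states(s$eeg, s$emg)
  expect_identical(h1$state, h2$state)
  expect_identical(ma_intervals(h1), ma_intervals(h2))
})

test_that("constant EMG triggers an informative error", {
  fx <- gc_fixture()
  const_emg <- tibble::tibble(t = fx$session$emg$t, value = 0)
  attr(const_emg, "fs") <- 1017
  expect_error(score_states(fx$session$eeg, const_emg), regexp = "emg_thresh")
})

test_that("wake bouts of 16 s are not microarousals, shorter EMG-burst bouts are", {
  # hand-built: NREM with a 16 s and an 8 s wake bout
  hyp <- make_hyp(c(nrem = 120, wake = 16, nrem = 120, wake = 8, nrem = 120))
  fs <- 200
  n <- 384 * fs
  emg <- withr::with_seed(3, rnorm(n, sd = 0.1))
  # EMG bursts inside both bouts
  burst <- function(emg, from, to) {
    idx <- (from * fs):(to * fs)
    emg[idx] <- rnorm(length(idx), sd = 2)
    emg
  }
  emg <- burst(emg, 120, 136)
  emg <- burst(emg, 256.5, 264)
  hyp2 <- detect_microarousals(hyp, emg, fs_emg = fs)
  iv <- ma_intervals(hyp2)
  expect_equal(nrow(iv), 1)
  # onset within one bin of the burst start
  expect_lt(abs(iv$onset - 256.5), 2)
  expect_true(all(hyp2$state[hyp2$bin_start >= 120 & hyp2$bin_start < 136] == "wake"))
})

test_that("bouts without an EMG burst are not confirmed", {
  hyp <- make_hyp(c(nrem = 120, wake = 8, nrem = 120, wake = 8, nrem = 120))
  fs <- 200
  emg <- withr::with_seed(4, rnorm(376 * fs, sd = 0.1))
  idx <- (248 * fs):(256 * fs)
  emg[idx] <- rnorm(length(idx), sd = 2) # burst only in the second bout
  hyp2 <- detect_microarousals(hyp, emg, fs_emg = fs)
  expect_equal(nrow(ma_intervals(hyp2)), 1)
  expect_gt(ma_intervals(hyp2)$onset, 240)
})

test_that("MA intervals respect the <15 s and NREM-flanking invariants", {
  fx <- gc_fixture()
  iv <- ma_intervals(fx$hyp)
  if (nrow(iv)) {
    expect_true(all(iv$end - iv$start < 15))
    for (i in seq_len(nrow(iv))) {
      before <- state_at(fx$hyp, iv$start[i] - 1)
      after <- state_at(fx$hyp, iv$end[i] + 1)
      expect_equal(before, "nrem")
      expect_equal(after, "nrem")
    }
  }
})

test_that("state scoring recovers the ground truth on synthetic sessions", {
  fx <- gc_fixture()
  ex <- fx$truth$state != "ma" & fx$hyp$state != "ma"
  agree <- mean((fx$hyp$state == fx$truth$state)[ex])
  expect_gte(agree, 0.9)
})

test_that("detected MA onsets match the programmed onsets", {
  fx <- gc_fixture()
  true_on <- fx$session$states$ma$onset
  det_on <- ma_intervals(fx$hyp)$onset
  if (length(true_on)) {
    hit <- vapply(true_on, function(x) any(abs(det_on - x) <= 2), logical(1))
    expect_gte(mean(hit), 0.85)
  }
})

test_that("state_durations sums to the session and counts MAs", {
  hyp <- make_hyp(c(wake = 100, nrem = 200, rem = 60))
  d <- state_durations(hyp)
  expect_equal(d$wake_s + d$nrem_s + d$rem_s + d$ma_s, 360)
  expect_equal(d$wake_s, 100)
  expect_equal(d$nrem_s, 200)
  expect_equal(d$rem_s, 60)
  expect_equal(d$ma_count, 0)

  ma_iv <- tibble::tibble(start = 150, end = 158, onset = 150.5)
  hyp2 <- make_hyp(c(wake = 100, nrem = 50, ma = 8, nrem = 142, rem = 60), ma = ma_iv)
  d2 <- state_durations(hyp2)
  expect_equal(d2$ma_count, 1)
  expect_equal(d2$ma_s, 8)
  expect_equal(d2$ma_per_h_nrem, 1 / ((192 + 8) / 3600))
})

test_that("NREM fraction of scored sessions matches the generator design", {
  fx <- gc_fixture()
  d <- state_durations(fx$hyp)
  frac <- (d$nrem_s + d$ma_s) / sum(d$wake_s + d$nrem_s + d$rem_s + d$ma_s)
  truth_frac <- fx$session$states$total_nrem_s / fx$session$params$duration_s
  expect_lt(abs(frac - truth_frac), 0.05)
})
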