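# Synthetic session generator: determinism, architecture, band structure,
# and programmed event statistics.

test_that("identical (params, seed) give bit-identical sessions", {
  p <- short_params("gc", 900)
  a <- simulate_session(p, seed = 7)
  b <- simulate_session(p, seed = 7)
  expect_identical(a$states, b$states)
  expect_identical(a$eeg, b$eeg)
  expect_identical(a$photometry, b$photometry)
  c <- simulate_session(p, seed = 8)
  expect_false(identical(a$photometry$f465, c$photometry$f465))
})

test_that("state intervals tile the session and MAs sit inside NREM", {
  for (seed in 1:5) {
    st <- withr::with_seed(seed, generate_states(short_params("gc", 1500)))
    iv <- st$intervals
    expect_equal(iv$start[1], 0)
    expect_equal(iv$end[nrow(iv)], 1500)
    expect_equal(iv$start[-1], iv$end[-nrow(iv)])
    if (nrow(st$ma)) {
      nrem <- iv[iv$state == "nrem", ]
      inside <- vapply(seq_len(nrow(st$ma)), function(i) {
        any(st$ma$onset[i] > nrem$start &
          st$ma$onset[i] + st$ma$duration[i] < nrem$end)
      }, logical(1))
      expect_true(all(inside))
      expect_true(all(st$ma$duration < 15))
    }
    expect_true(all(diff(st$cycles$onset) > 0))
  }
})

test_that("zero MA rate and zero coupling give no microarousals", {
  st <- withr::with_seed(1, generate_states(
    short_params("gc", 1200, ma_rate_per_min_nrem = 0, trough_ma_coupling_p = 0)
  ))
  expect_equal(nrow(st$ma), 0)
})

test_that("zero ISO amplitude schedules no cycles and records no troughs", {
  p <- short_params("gc", 1200, iso_amp_z = 0)
  s <- simulate_session(p, seed = 3)
  expect_equal(nrow(s$states$cycles), 0)
})

test_that("trough spacing within an epoch follows the programmed period", {
  s <- simulate_session(short_params("gc", 3000), seed = 9)
  cyc <- s$states$cycles
  gaps <- diff(cyc$extremum_time)
  period <- 60 / s$params$iso_freq_cpm
  # spacing within an epoch is exactly one period; across epochs larger
  within <- gaps[gaps < 2 * period]
  expect_true(all(abs(within - period) < 1e-6))
})

test_that("sessions too short or without NREM fail loudly", {
  expect_error(generate_states(short_params("gc", 1200, duration_s = 500)),
    regexp = "600 s"
  )
})

test_that("NREM fraction across sessions matches the dwell-time design", {
  # Monte-Carlo over the semi-Markov architecture; expectation for
  # wake/NREM/REM means 150/180/75 with p_rem = 0.5 is ~0.49
  fr <- vapply(1:12, function(seed) {
    st <- withr::with_seed(seed, generate_states(short_params("gc", 2400)))
    st$total_nrem_s / 2400
  }, numeric(1))
  expect_gt(mean(fr), 0.4)
  expect_lt(mean(fr), 0.7)
})

test_that("realized trough-MA coupling matches the programmed probability", {
  tot <- 0L
  coup <- 0L
  for (seed in 1:20) {
    st <- withr::with_seed(seed, generate_states(short_params("gc", 2400)))
    tot <- tot + nrow(st$cycles)
    coup <- coup + sum(st$cycles$coupled)
  }
  p_hat <- coup / tot
  se <- sqrt(0.29 * 0.71 / tot)
  expect_lt(abs(p_hat - 0.29), 3 * se + 1e-9)
})

test_that("EEG band content follows the state: NREM delta, REM theta", {
  p <- short_params("gc", 600)
  # force a single-state track by hand
  st_nrem <- list(
    intervals = tibble::tibble(start = 0, end = 600, state = "nrem"),
    ma = tibble::tibble(onset = numeric(0), duration = numeric(0), coupled = logical(0)),
    cycles = tibble::tibble(onset = numeric(0), extremum_time = numeric(0), coupled = logical(0))
  )
  sig <- withr::with_seed(1, generate_eeg_emg(p, st_nrem))
  sp <- compute_spectrogram(sig$eeg, p$fs_eeg, max_freq = 30)
  expect_true(all(band_power(sp, c(0.5, 4)) > band_power(sp, c(6, 9))))

  st_rem <- st_nrem
  st_rem$intervals$state <- "rem"
  sig_r <- withr::with_seed(1, generate_eeg_emg(p, st_rem))
  sp_r <- compute_spectrogram(sig_r$eeg, p$fs_eeg, max_freq = 30)
  td <- band_power(sp_r, c(6, 9)) / band_power(sp_r, c(0.5, 4))
  expect_gt(mean(td > 1), 0.9)
})

test_that("EMG bursts during MAs exceed flanking NREM activity", {
  st <- list(
    intervals = tibble::tibble(start = 0, end = 600, state = "nrem"),
    ma = tibble::tibble(onset = 300, duration = 10, coupled = FALSE),
    cycles = tibble::tibble(onset = numeric(0), extremum_time = numeric(0), coupled = logical(0))
  )
  p <- short_params("gc", 600)
  sig <- withr::with_seed(2, generate_eeg_emg(p, st))
  emg <- sig$emg$value
  fs <- p$fs_eeg
  rms <- function(a, b) sqrt(mean(emg[(a * fs):(b * fs)]^2))
  expect_gt(rms(302, 308), 2 * rms(280, 295))
  expect_gt(rms(302, 308), 2 * rms(315, 330))
})

test_that("shared artifact correlates the raw channels before correction", {
  # activity off: the shared artifact at 5x the sensor noise dominates both
  # channels, so the raw pair is strongly correlated before the isosbestic
  # regression removes it
  p <- short_params("gc", 900,
    artifact_sd = 5 * 0.3, iso_amp_z = 0, noise_sd = 0,
    state_offsets = c(wake = 0, nrem = 0, rem = 0)
  )
  s <- simulate_session(p, seed = 5)
  expect_gt(cor(s$photometry$f465, s$photometry$f405), 0.8)
})

test_that("serotonin sessions order state means wake > NREM > REM", {
  s <- simulate_session(short_params("sert", 1800), seed = 6)
  th <- truth_hypnogram(s$states, 1800)
  st <- state_at(th, s$photometry$t)
  z <- s$latent
  m_w <- mean(z[st == "wake"])
  m_n <- mean(z[st %in% c("nrem", "ma")])
  m_r <- mean(z[st == "rem"])
  expect_gt(m_w, m_n)
  expect_gt(m_n, m_r)
})

test_that("generate_serotonin mirrors the serotonin photometry site", {
  p <- short_params("sert", 900)
  st <- withr::with_seed(2, generate_states(p))
  a <- withr::with_seed(3, generate_serotonin(p, st))
  b <- withr::with_seed(3, generate_photometry(p, st, site = "serotonin"))
  expect_identical(a$latent, b$latent)
})

test_that("serotonin peak schedule matches the programmed rate", {
  rate <- vapply(1:6, function(seed) {
    s <- simulate_session(short_params("sert", 3000), seed = seed)
    nrem_min <- s$states$total_nrem_s / 60
    nrow(s$states$cycles) / nrem_min
  }, numeric(1))
  # schedule density is the programmed rate minus the epoch-edge margin
  expect_lt(abs(mean(rate) - 1.14), 0.12)
})

test_that("two-photon labels reproduce programmed fractions exactly", {
  p <- short_params("2p_gc", 900)
  s <- simulate_session(p, seed = 4)
  tab <- table(s$cell_labels$label)
  expect_equal(unname(tab[["up"]]), round(0.50 * p$n_cells))
  expect_equal(unname(tab[["down"]]), round(0.22 * p$n_cells))
})

test_that("all-up populations have higher NREM rates by construction", {
  p <- short_params("2p_gc", 900, frac_up = 1, frac_down = 0, n_cells = 12)
  s <- simulate_session(p, seed = 8)
  th <- truth_hypnogram(s$states, 900)
  st <- state_at(th, unique(s$cells$t))
  qw <- st == "wake"
  nr <- st == "nrem"
  ok <- vapply(split(s$cells$raw - s$cells$neuropil, s$cells$cell_id), function(res) {
    mean(res[nr]) > mean(res[qw])
  }, logical(1))
  expect_gt(mean(ok), 0.9)
})

test_that("velocity is strictly positive only inside locomotion bouts", {
  s <- simulate_session(short_params("2p_gc", 900, n_cells = 10), seed = 2)
  v <- s$velocity$value
  th <- truth_hypnogram(s$states, 900)
  st <- state_at(th, s$velocity$t)
  expect_true(all(v[st != "wake"] == 0))
  expect_true(any(v > 0))
})
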