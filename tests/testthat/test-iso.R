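# Infraslow spectral quantification.

test_that("a pure 1.5 cpm tone peaks in every window and dominates the band", {
  t <- 0:1199
  z <- tibble::tibble(t = t + 0.5, z = sin(2 * pi * 1.5 / 60 * t))
  attr(z, "fs") <- 1
  sp <- iso_spectrogram(z)
  peak_f <- sp$freqs[apply(sp$power, 1, which.max)]
  expect_true(all(abs(peak_f - 1.5) <= 0.5))

  hyp <- make_hyp(c(nrem = 1200))
  pw <- state_iso_power(sp, hyp, states = "nrem")
  expect_gte(pw$rel_band_power[1], 0.9)
})

test_that("constant input gives zero infraslow power", {
  z <- tibble::tibble(t = 0:599 + 0.5, z = rep(1, 600))
  attr(z, "fs") <- 1
  sp <- iso_spectrogram(z)
  expect_true(all(sp$power < 1e-20))
  expect_error(iso_spectrogram(rnorm(60)), regexp = "120")
})

test_that("white noise spreads power across the infraslow range", {
  z <- tibble::tibble(t = 0:2399 + 0.5, z = withr::with_seed(5, rnorm(2400)))
  attr(z, "fs") <- 1
  sp <- iso_spectrogram(z)
  hyp <- make_hyp(c(nrem = 2400))
  pw <- state_iso_power(sp, hyp, states = "nrem")
  # flat-spectrum expectation: band fraction = (# bins in 1-2) / (# bins in 0-6)
  nb <- sum(sp$freqs >= 1 & sp$freqs <= 2)
  nt <- sum(sp$freqs > 1e-9 & sp$freqs <= 6)
  expect_lt(abs(pw$rel_band_power[1] - nb / nt), 0.1)
  # no fixed frequency bin dominates across windows (no persistent peak)
  med <- apply(sp$power, 1, median)
  per_bin <- colMeans(sp$power > 3 * med)
  expect_true(all(per_bin < 0.5))
})

test_that("relative band power is invariant to affine rescaling", {
  fx <- gc_fixture()
  sp1 <- iso_spectrogram(fx$z1)
  z2 <- fx$z1
  z2$z <- 7.3 * z2$z - 2
  attr(z2, "fs") <- 1
  sp2 <- iso_spectrogram(z2)
  a <- state_iso_power(sp1, fx$hyp)
  b <- state_iso_power(sp2, fx$hyp)
  expect_equal(a$rel_band_power, b$rel_band_power, tolerance = 1e-9)
})

test_that("NREM carries more relative ISO band power than wake", {
  fx <- gc_fixture()
  sp <- iso_spectrogram(fx$z1)
  pw <- state_iso_power(sp, fx$hyp)
  nrem <- pw$rel_band_power[pw$state == "nrem"]
  wake <- pw$rel_band_power[pw$state == "wake"]
  expect_false(is.na(nrem))
  if (!is.na(wake)) expect_gt(nrem, wake)
})

test_that("absent states give NA rather than an error", {
  z <- tibble::tibble(t = 0:599 + 0.5, z = withr::with_seed(1, rnorm(600)))
  attr(z, "fs") <- 1
  sp <- iso_spectrogram(z)
  hyp <- make_hyp(c(nrem = 600))
  pw <- state_iso_power(sp, hyp)
  expect_true(is.na(pw$rel_band_power[pw$state == "rem"]))
})

test_that("ISO peak frequency is recovered across programmed rates", {
  ok <- 0L
  n <- 0L
  for (f in c(1.0, 1.5, 2.0)) {
    for (seed in 1:2) {
      s <- simulate_session(short_params("gc", 1800, iso_freq_cpm = f), seed = seed)
      hyp <- score_states(s$eeg, s$emg)
      z1 <- downsample_1hz(process_photometry(s$photometry))
      sp <- iso_spectrogram(z1)
      pw <- state_iso_power(sp, hyp, states = "nrem")
      spectra <- attr(pw, "spectra")
      nondc <- spectra$freq_cpm > 1e-9
      peak <- spectra$freq_cpm[nondc][which.max(spectra$power[nondc])]
      n <- n + 1L
      if (abs(peak - f) <= 0.5) ok <- ok + 1L
    }
  }
  expect_gte(ok / n, 0.9)
})

test_that("stage rules assign T0/T1/T2 according to epoch structure", {
  # wake 360 s (> 5 min) then a 3 min NREM epoch; then short wake and a
  # 90 s epoch (no T2)
  hyp <- make_hyp(c(wake = 360, nrem = 180, wake = 60, nrem = 90, wake = 30))
  z <- tibble::tibble(t = 0:719 + 0.5, z = withr::with_seed(2, rnorm(720)))
  attr(z, "fs") <- 1
  st <- stage_analysis(z, hyp)
  e1 <- st[st$epoch == 1, ]
  expect_setequal(e1$stage, c("T0", "T1", "T2"))
  e2 <- st[st$epoch == 2, ]
  expect_setequal(e2$stage, "T1") # epoch < 120 s and prior wake < 5 min
  expect_true(all(st$power >= 0))
  expect_true(all(st$amplitude >= 0))
})

test_that("stationary ISO shows no systematic T1 vs T2 power difference", {
  t1 <- c()
  t2 <- c()
  for (seed in 1:8) {
    s <- simulate_session(short_params("gc", 1800), seed = seed + 100)
    hyp <- score_states(s$eeg, s$emg)
    z1 <- downsample_1hz(process_photometry(s$photometry))
    st <- stage_analysis(z1, hyp)
    both <- intersect(st$epoch[st$stage == "T1"], st$epoch[st$stage == "T2"])
    if (length(both)) {
      t1 <- c(t1, st$power[st$stage == "T1" & st$epoch %in% both])
      t2 <- c(t2, st$power[st$stage == "T2" & st$epoch %in% both])
    }
  }
  expect_gt(length(t1), 5)
  expect_gt(t.test(t1, t2, paired = TRUE)$p.value, 0.05)
})

test_that("sigma cross-correlation localises constructed lags", {
  fx <- gc_fixture()
  spec <- compute_spectrogram(fx$session$eeg, 1017, max_freq = 30)
  hyp <- make_hyp(c(nrem = 1800))
  # sigma track equal to z itself: r(0) = 1
  fake <- spec
  z_on_windows <- approx(fx$z1$t, fx$z1$z, xout = spec$times, rule = 2)$y
  sel <- which(spec$freqs >= 10 & spec$freqs <= 15)
  fake$power[, sel] <- matrix(z_on_windows, nrow(fake$power), length(sel))
  cc <- sigma_crosscorr(fx$z1, fake, hyp)
  expect_equal(cc$r[cc$lag_s == 0], 1, tolerance = 1e-6)

  # shifted by +10 s: argmax at +10 +/- 2
  shift_k <- as.integer(10 / spec$step_s)
  shifted <- c(rep(z_on_windows[1], shift_k), head(z_on_windows, -shift_k))
  fake$power[, sel] <- matrix(shifted, nrow(fake$power), length(sel))
  cc2 <- sigma_crosscorr(fx$z1, fake, hyp)
  expect_lt(abs(cc2$lag_s[which.max(cc2$r)] - 10), 2 + 1e-9)

  # independent noise: |r| small everywhere
  fake$power[, sel] <- matrix(
    withr::with_seed(9, rnorm(nrow(fake$power) * length(sel))),
    nrow(fake$power), length(sel)
  )
  cc3 <- sigma_crosscorr(fx$z1, fake, hyp)
  expect_lt(max(abs(cc3$r), na.rm = TRUE), 0.15)
})
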