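# Trough/peak detection, outcome classification, PSTH latency and drop.

test_that("moving baseline tracks constants, ramps, and attenuates the ISO band", {
  expect_equal(moving_baseline(rep(4, 300), fs = 1), rep(4, 300))

  ramp <- 0.01 * (0:599)
  mb <- moving_baseline(ramp, fs = 1)
  mid <- 40:560
  # centered mean of a line tracks it up to the half-sample window asymmetry
  expect_lt(max(abs(mb[mid] - ramp[mid])), 0.01)
  expect_lt(max(abs(mb - ramp)), 0.01 * 60 / 2)

  # 1.5 cpm sine, span = 1.5 periods: |sinc| attenuation
  t <- 0:999
  f <- 1.5 / 60
  x <- sin(2 * pi * f * t)
  mb2 <- moving_baseline(x, fs = 1, span_s = 60)
  expected <- abs(sin(pi * f * 60) / (pi * f * 60))
  expect_lt(max(abs(mb2[100:900])), expected + 0.02)
})

test_that("a constant trace yields zero events", {
  hyp <- make_hyp(c(nrem = 600))
  z <- tibble::tibble(t = 0:599 + 0.5, z = rep(0, 600))
  attr(z, "fs") <- 1
  ev <- detect_events(z, hyp, "trough", sd_ref = 1)
  expect_equal(nrow(ev), 0)
})

test_that("detected troughs recover programmed trough times and rate", {
  fx <- gc_fixture()
  ev <- detect_events(fx$z1, fx$hyp, "trough")
  truth_t <- fx$session$states$cycles$extremum_time
  hit <- vapply(truth_t, function(x) any(abs(ev$time - x) <= 3), logical(1))
  expect_gte(mean(hit), 0.85)

  d <- state_durations(fx$hyp)
  rate <- nrow(ev) / ((d$nrem_s + d$ma_s) / 60)
  expect_lt(abs(rate - fx$session$params$iso_freq_cpm), 0.35)
})

test_that("raising the threshold never increases the event count", {
  fx <- gc_fixture()
  counts <- vapply(c(0.1, 0.2, 0.4, 0.8, 1.2, 2), function(th) {
    nrow(detect_events(fx$z1, fx$hyp, "trough", thresh_sd = th))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("outcome classification follows the first state change", {
  # continuous NREM, no MA: everything maintained
  hyp <- make_hyp(c(nrem = 600))
  ev <- structure(
    tibble::tibble(time = c(100, 300, 500), magnitude = 1),
    class = c("event_set", class(tibble::tibble()))
  )
  out <- classify_outcomes(ev, hyp)
  expect_true(all(out$outcome == "nrem_maintained"))
  pct <- outcome_percentages(out)
  expect_equal(sum(pct$pct), 100)
  expect_equal(unname(pct$pct[pct$outcome == "nrem_maintained"]), 100)

  # event 1 s before a REM onset
  hyp2 <- make_hyp(c(nrem = 300, rem = 100, nrem = 200))
  ev2 <- structure(
    tibble::tibble(time = 299, magnitude = 1),
    class = c("event_set", class(tibble::tibble()))
  )
  expect_equal(classify_outcomes(ev2, hyp2)$outcome, "rem")

  # MA onsets, sustained-wake onsets and quiet stretches each classify
  ma_iv <- tibble::tibble(start = 200, end = 208, onset = 200.5)
  hyp3 <- make_hyp(c(nrem = 200, ma = 8, nrem = 92, wake = 100), ma = ma_iv)
  ev3 <- structure(
    tibble::tibble(time = c(195, 290, 150), magnitude = 1),
    class = c("event_set", class(tibble::tibble()))
  )
  out3 <- classify_outcomes(ev3, hyp3)
  expect_equal(out3$outcome, c("ma", "wake", "nrem_maintained"))
})

test_that("outcome percentages sum to 100 on generated sessions", {
  fx <- gc_fixture()
  ev <- classify_outcomes(detect_events(fx$z1, fx$hyp, "trough"), fx$hyp)
  expect_equal(sum(outcome_percentages(ev)$pct), 100, tolerance = 1e-9)
})

test_that("psth averages snippets on the aligned grid", {
  z <- tibble::tibble(t = (0:9999) / 10, z = rep(0, 10000))
  attr(z, "fs") <- 10
  ps <- psth(z, onsets = c(100, 300, 500), pre_s = 15, post_s = 15)
  expect_equal(ps$n_events, 3)
  expect_true(all(ps$mean == 0))

  zz <- z
  zz$z <- sin(2 * pi * 0.02 * zz$t)
  ps1 <- psth(zz, onsets = 200)
  expect_equal(ps1$mean, sin(2 * pi * 0.02 * (200 + ps1$time)), tolerance = 1e-6)

  expect_error(psth(z, onsets = 2), regexp = "full PSTH window")
})

test_that("latency is exact on constructed noise-free declines", {
  fs <- 10
  tt <- seq(-15, 15, by = 1 / fs)
  for (onset in c(-6, -8.5, -4.3)) {
    trace <- ifelse(tt < onset, 0, -(tt - onset) * 0.5)
    trace <- pmax(trace, -2.5)
    ps <- structure(
      list(time = tt, mean = trace, n_events = 5, sd_ref = 1, fs = fs),
      class = "psth"
    )
    res <- latency_and_drop(ps, thresh_sd = 0.05)
    # exact up to the interpolated crossing: dev(t) = baseline + 0.5 (t - onset)
    baseline <- mean(trace[tt >= -15 & tt <= -5])
    cross <- onset + (0.05 - baseline) / 0.5
    expect_equal(res$latency_s, -cross, tolerance = 1 / fs)
    expect_equal(res$drop_z, baseline + 2.5, tolerance = 1e-9)
    expect_true(res$onset_defined)
  }
})

test_that("flat traces flag latency as undefined but report the drop", {
  ps <- structure(
    list(
      time = seq(-15, 15, 0.1), mean = rep(0, 301), n_events = 3,
      sd_ref = 1, fs = 10
    ),
    class = "psth"
  )
  res <- latency_and_drop(ps)
  expect_true(is.na(res$latency_s))
  expect_false(res$onset_defined)
  expect_equal(res$drop_z, 0, tolerance = 1e-12)
})

test_that("session PSTH latency recovers the programmed decline-to-MA lag", {
  fx <- gc_fixture()
  on <- ma_intervals(fx$hyp)$onset
  ps <- psth(fx$proc, on)
  res <- latency_and_drop(ps, direction = "down")
  expect_true(res$onset_defined)
  expect_lt(abs(res$latency_s - fx$session$params$trough_to_ma_lag_s), 1)
})
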