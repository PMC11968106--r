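# Shared fixtures: short synthetic sessions built once per test run.
# Durations are kept well below the defaults so the unit suite stays fast;
# the acceptance suite exercises full-length sessions.

short_params <- function(preset = "gc", duration_s = 1200, ...) {
  session_params(preset, duration_s = duration_s, ...)
}

# Memoised short GC session + derived objects used across test files.
gc_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- simulate_session(short_params("gc", 1800), seed = 42)
      hyp <- score_states(s$eeg, s$emg)
      proc <- process_photometry(s$photometry)
      cache <<- list(
        session = s, hyp = hyp, proc = proc,
        z1 = downsample_1hz(proc),
        truth = truth_hypnogram(s$states, s$params$duration_s)
      )
    }
    cache
  }
})

# Hand-built hypnogram from a run-length specification, e.g.
# make_hyp(c(wake = 60, nrem = 300, rem = 40)).
make_hyp <- function(spec, bin_s = 2, ma = NULL) {
  state <- rep(names(spec), times = as.integer(spec / bin_s))
  h <- infraslow:::new_hypnogram(
    bin_start = (seq_along(state) - 1) * bin_s,
    state = state, bin_s = bin_s, ma_intervals = ma
  )
  h
}
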