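---
title: "Methods: infraslow oscillation analysis for sleep recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: infraslow oscillation analysis for sleep recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`infraslow` analyses the ~1–2 cycles/min infraslow oscillation (ISO) seen in
population calcium and neuromodulator (5-HT) signals during NREM sleep in
rodents, and its coupling to microarousals (MAs). The pipeline has four
stages:

1. **Sleep scoring** (`score_states()`, `detect_microarousals()`): wake/NREM/
   REM in 2 s bins from the EEG spectrogram (5 s window, 2 s step) and the
   EMG envelope, then MA detection (<15 s wake bouts flanked by NREM,
   confirmed by an EMG burst above mean + 0.5 SD of the envelope).
2. **Photometry preprocessing** (`process_photometry()`): 2 Hz zero-phase
   low-pass of both channels, least-squares fit of the isosbestic 405 nm
   reference to the 465 nm signal to form the baseline F0,
   dF/F = (F − F0)/F0, per-session z-score, and 1 s block-mean downsampling
   (`downsample_1hz()`).
3. **ISO quantification**: sliding-window Fourier power of the 1 Hz z-trace
   over 0–6 cycles/min (2 min window, 2 s step; `iso_spectrogram()`,
   `state_iso_power()`), NREM-stage (T0/T1/T2) power and amplitude
   (`stage_analysis()`), sigma-band cross-correlation (`sigma_crosscorr()`).
4. **Event statistics**: troughs/peaks against a 60 s moving baseline with a
   0.2 SD threshold (`detect_events()`), state-transition outcomes within a
   15 s lookahead (`classify_outcomes()`), and MA-aligned PSTH latency/drop
   (`psth()`, `latency_and_drop()`: baseline −15…−5 s, 0.05 SD onset
   threshold).

Two further tracks cover dual-site recordings (`align_signals()`,
`state_correlation()`) and two-photon populations (`neuropil_dff()`,
`classify_cells()`, `ma_aligned_activity()`).

Because raw in-vivo recordings of this kind are not redistributable, the
package ships a synthetic session generator (`session_params()`,
`simulate_session()`) with full ground truth; every headline quantity is
validated by *parameter recovery*: the generator programs a value, the full
pipeline must read it back.

# The synthetic generator

## What it emulates

* **Sleep architecture**: a semi-Markov chain wake → NREM → {wake, REM},
  REM → wake, with exponential dwell times truncated below at 20/30/10 s and
  means 150/180/75 s (wake/NREM/REM), REM following NREM with probability
  0.5. These give a NREM fraction near 0.5, mean NREM bouts of ~3 min and a
  ~10% REM fraction — typical mouse light-phase sleep. Only this gross
  architecture matters for recovery; no ultradian structure is modelled.
* **EEG/EMG**: sums of band-limited Gaussian noise (delta 0.5–4, theta 6–9,
  sigma 10–15 Hz, desynchronised 0.5–30 Hz background) with state-dependent
  weights (NREM delta-dominated, REM theta-dominated), and a 30–300 Hz EMG
  carrier whose envelope is high in wake/MA and low in sleep.
* **ISO**: within each NREM epoch, cycles at the programmed rate
  (1.5 cycles/min granule-cell-like, 1.3 mossy-cell-like) with a random
  per-epoch phase. The waveform is a plateau with sharp piecewise-linear
  excursions (3 s decline/rise, 5 s recovery) rather than a sinusoid: the
  recorded signals show fast drops against a slowly varying plateau, and a
  sharp decline is what makes the Methods-style decline-onset latency
  well defined. The serotonin preset mirrors this with upward phasic peaks
  (1.14 cycles/min) on a low NREM baseline, state means ordered
  wake > NREM > REM.
* **Microarousals**: a programmed fraction of cycles (0.29 GC, 0.30 MC for
  troughs; 0.35 for 5-HT peaks) are *coupled*: the MA onset is placed at the
  programmed lag (6.06 / 5.18 / 6.82 s) after the cycle's decline/rise
  onset. The remaining MAs are placed uniformly in NREM so the total MA rate
  is 0.5/min of NREM. Durations are drawn uniformly from 5–12 s (< 15 s by
  definition). Coupled cycles are a fixed count, `round(p * n)`, sampled
  among the cycles that can host an MA (stratified placement): this keeps the
  session-level coupled fraction at the programmed value up to rounding,
  rather than adding binomial noise on top of the recovery error being
  measured.
* **Lag semantics**: the programmed lag runs from the *decline onset* to the
  MA onset, matching the definition of the latency estimator the pipeline
  uses. With the 3 s decline this keeps the trough itself ahead of the MA,
  so "troughs precede MAs" holds as well; with a sharp decline the two
  descriptions nearly coincide, which is the only reading under which both
  are simultaneously true.
* **Photometry rendering**: the latent z-trace (state offsets + gated ISO +
  Ornstein–Uhlenbeck noise, SD 0.1 z, correlation time 8 s) modulates a
  465 nm channel (5% per z-unit) with multiplicative exponential bleaching
  (tau 10 h, i.e. ~10%/h), a band-limited (0.05–0.5 Hz) motion artifact
  shared with the 405 nm channel at channel-specific gains (2% of baseline),
  and white sensor noise. The 405 channel carries no activity, so the
  isosbestic regression is non-trivial but solvable.
* **Two-photon populations**: per cell, Poisson calcium transients
  (instantaneous rise, 1.5 s exponential decay, GCaMP6s-like) whose rate is
  scaled ×4 (up cells) or ×0.25 (down cells) in NREM versus a 0.06 Hz quiet-
  wake rate; up cells are silenced during MAs; neuropil is a shared slow
  background; velocity is positive only in locomotion bouts inside wake.
  Labels are assigned deterministically so programmed fractions (50/22%
  GC-like, 28/10% MC-like) are exact.

## What it does not emulate

No biophysical EEG (no spindles, slow-wave shape, dentate spikes), no
ultradian or circadian structure, no receptor pharmacology, no imaging-plane
artifacts, and the ISO waveform is stereotyped. Passing recovery tests
therefore demonstrates that the *pipeline* is correct and unbiased under the
assumed signal structure — not that it would be robust to every pathology of
real recordings (electrode artifacts, state transitions missed by EEG,
sensor saturation).

# Numerical and design choices

* **EMG threshold**: the per-bin RMS distribution of a sleep session is
  strongly bimodal. A fixed percentile (e.g. the 60th) lands inside the wake
  cluster whenever the wake fraction approaches that percentile,
  fragmenting genuine wake bouts into short remnants that masquerade as
  MAs. The default is therefore a deterministic two-means split of log RMS
  (threshold at the geometric mean of the cluster centers), overridable via
  `emg_thresh`. The theta/delta REM threshold is 1.5.
* **Label smoothing**: single-bin flicker (a bin whose two neighbours agree
  and differ from it) is relabelled before bout extraction, standing in for
  the manual validation step of semi-automatic scoring.
* **Reference fit**: the default fit of the 405 channel includes a linear
  time regressor (`fit_reference(detrend = TRUE)`). Over a session the
  bleach trend is a single slow degree of freedom; any chance correlation
  between it and the activity signal otherwise perturbs the fitted slope
  (errors of ±0.5 were observed on hour-long simulations) and leaks the
  shared motion artifact into dF/F as slow noise. The time term absorbs the
  bleach direction; `detrend = FALSE` gives the classical two-parameter fit.
* **Filtering**: 4th-order Butterworth applied forward–backward (zero phase
  — phase lag would bias every latency), with reflection padding because
  `filtfilt` itself does not pad and its edge transients can corrupt the
  reference fit.
* **Event detection**: the 60 s moving baseline is computed over
  NREM-context samples only (a plain moving average bleeds the neighbouring
  state's offset into the first/last half-window of each epoch); excursions
  must exceed the threshold for ≥ 4 s (infraslow events do; single misscored
  2 s bins do not); excursions separated by < 10 s merge; and the extremum
  must be flanked by ≥ 4 s of NREM context on both sides — an extremum at
  the epoch edge is the state transition itself, not an intra-NREM phasic
  event. The threshold SD is the session SD of the z-trace (= 1), declared
  and configurable via `sd_ref`.
* **Latency estimation**: on the MA-aligned mean trace, the baseline is the
  mean over −15…−5 s; the onset is found by walking *back* from the trace
  extremum to the last sample within 0.05 SD of baseline, with linear
  interpolation of the crossing. A forward search for the first crossing is
  unusable on finite-session means (noise excursions before the true decline
  capture it); the backward search identifies the onset of *the* decline
  that ends in the trough and is exact on noise-free declines.
* **Window-to-state assignment**: a 2 min spectral window counts toward a
  state when ≥ 80% of its span carries that label; MA bins count as NREM
  context throughout (the ISO spans MAs), except that state *means* and
  dual-site correlations exclude MA bins from NREM by default.
* **Relative ISO power**: power in 1–2 cycles/min divided by total power
  over 0–6 cycles/min, both excluding the DC bin; windows are mean-removed
  and Hann-tapered (suppresses leakage from state-offset steps).
* **Stage analysis**: T1 = first minute of every NREM epoch; T2 = last
  minute of epochs ≥ 2 min; T0 = first minute of epochs preceded by > 5 min
  of contiguous wake. "Amplitude" is the peak-to-trough range of the
  1–2 cycles/min band-passed z within the minute (the quantity is not
  otherwise pinned down).
* **Two-photon classification**: Welch's t-test on per-bin mean dF/F between
  NREM and quiet wake. Bins are 5 s — long relative to the 1.5 s transient
  decay, so neighbouring bin means are effectively independent and the
  type-I rate stays near alpha (2 s bins inflate it noticeably). Quiet wake
  = wake bins with velocity < 0.5 cm/s throughout. Alpha is 0.05 with no
  multiplicity correction, matching per-cell classification practice.
  The minimax baseline is a 60 s morphological opening (rolling minimum
  then maximum) of the 5 s-smoothed trace.
* **Outcome lookahead**: an event's outcome is the first state change within
  15 s (configurable); with observed latencies of ~5–7 s this is latency
  plus margin.

# Validation problem sizes

The packaged acceptance run (`scripts/acceptance.R`) regenerates the full
study-scale experiments: 20 one-hour GC sessions, 12 MC and 14 serotonin
sessions (all at 1017 Hz EEG / 100 Hz photometry), and two 200-cell
45-minute two-photon populations. The unit/property suite uses 15–30 min
sessions and smaller populations; both scales use the same defaults, and
the quantities recovered are identical within sampling error.

# Known limitations

* The latency estimator carries a small (~0.1–0.3 s) downward bias from
  baseline-window contamination (the decline begins inside the −15…−5 s
  baseline window when the lag exceeds 5 s) and from dilution by uncoupled
  MAs; both are properties of the aligned-average method itself, not of the
  implementation, and sit well inside the recovery tolerance.
* Global z-scoring makes all event thresholds session-relative; sessions
  with very different state compositions therefore have slightly different
  absolute thresholds.
* The scorer is fully deterministic and has no notion of artifacts beyond
  thresholding; recordings with electrode noise would need pre-cleaning.
* `run_pipeline()` is deterministic given inputs and configuration; the
  generator is deterministic given `(params, seed)`.
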