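# Internal numeric helpers. These are deliberately dependency-free and O(n):
# the EEG traces they run on hold several million samples.

# Centered moving average; the window shrinks at the edges so the output has
# the same length as the input and no NA padding.
moving_average <- function(x, n) {
  n <- max(1L, as.integer(round(n)))
  if (n <= 1L) {
    return(as.numeric(x))
  }
  len <- length(x)
  h_lo <- (n - 1L) %/% 2L
  h_hi <- n - 1L - h_lo
  cs <- cumsum(c(0, as.numeric(x)))
  i <- seq_len(len)
  lo <- pmax(i - h_lo, 1L)
  hi <- pmin(i + h_hi, len)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Centered moving average over the samples where `mask` is TRUE; positions
# whose window contains no masked sample give NA. Used for state-contextual
# baselines, where averaging across a state boundary would bleed the
# neighbouring state's offset into the epoch edge.
masked_moving_average <- function(x, mask, n) {
  n <- max(1L, as.integer(round(n)))
  len <- length(x)
  m <- as.numeric(mask)
  cs <- cumsum(c(0, as.numeric(x) * m))
  cm <- cumsum(c(0, m))
  h_lo <- (n - 1L) %/% 2L
  h_hi <- n - 1L - h_lo
  i <- seq_len(len)
  lo <- pmax(i - h_lo, 1L)
  hi <- pmin(i + h_hi, len)
  cnt <- cm[hi + 1L] - cm[lo]
  out <- (cs[hi + 1L] - cs[lo]) / cnt
  out[cnt == 0] <- NA_real_
  out
}

# Centered rolling maximum via the van Herk/Gil-Werman decomposition
# (block-wise prefix/suffix cummax), O(n) regardless of window size.
# Edges are padded with the edge value.
roll_max <- function(x, n) {
  n <- max(1L, as.integer(round(n)))
  if (n <= 1L) {
    return(as.numeric(x))
  }
  x <- as.numeric(x)
  len <- length(x)
  h <- (n - 1L) %/% 2L
  xp <- c(rep(x[1L], h), x, rep(x[len], n - 1L - h))
  m <- length(xp)
  k <- as.integer(ceiling(m / n) * n)
  xp <- c(xp, rep(-Inf, k - m))
  bm <- matrix(xp, nrow = n)
  pref <- as.vector(apply(bm, 2L, cummax))
  suff <- as.vector(apply(bm[n:1L, , drop = FALSE], 2L, cummax)[n:1L, , drop = FALSE])
  i <- seq_len(m - n + 1L)
  pmax(suff[i], pref[i + n - 1L])[seq_len(len)]
}

roll_min <- function(x, n) {
  -roll_max(-x, n)
}

# Morphological opening (min then max), the classical rolling-floor baseline.
minimax_baseline <- function(x, n) {
  roll_max(roll_min(x, n), n)
}

# Gaussian noise band-limited to [lo, hi] Hz with unit standard deviation.
# Synthesised directly in the frequency domain (independent complex Gaussian
# coefficients on the in-band bins of a power-of-two grid), which is exact and
# avoids IIR instability at very low normalised frequencies.
band_limited_noise <- function(n, fs, lo, hi) {
  nf <- nextn(max(n, 2L), 2L)
  m <- nf %/% 2L
  f <- (1:(m - 1L)) * fs / nf
  inband <- which(f >= lo & f <= hi)
  if (length(inband) == 0) {
    abort("band_limited_noise: no frequency bins inside the requested band")
  }
  spec <- complex(length.out = nf)
  vals <- complex(real = rnorm(length(inband)), imaginary = rnorm(length(inband)))
  spec[1L + inband] <- vals
  spec[nf + 1L - inband] <- Conj(vals)
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  s <- sd(x)
  if (s == 0) x else x / s
}

# Stationary Ornstein-Uhlenbeck noise with correlation time `tau_s` seconds
# and stationary standard deviation `sd`. A 5*tau burn-in removes the
# zero-state transient.
ou_noise <- function(n, fs, tau_s, sd = 1) {
  if (sd <= 0) {
    return(numeric(n))
  }
  a <- exp(-1 / (fs * tau_s))
  burn <- as.integer(ceiling(5 * tau_s * fs))
  innov <- rnorm(n + burn, sd = sd * sqrt(1 - a^2))
  x <- as.numeric(stats::filter(innov, a, method = "recursive"))
  x[(burn + 1L):(burn + n)]
}

# Run-length encoding of a vector into (start index, end index, value).
index_runs <- function(x) {
  r <- rle(as.vector(x))
  ends <- cumsum(r$lengths)
  tibble(
    start = ends - r$lengths + 1L,
    end = ends,
    value = r$values
  )
}

# Linearly interpolated threshold crossing between samples i and i+1 of
# `dev` (crossing level `level`, times `t`). Assumes dev[i] <= level < dev[i+1].
interp_crossing <- function(t, dev, i, level) {
  if (i >= length(dev)) {
    return(t[length(t)])
  }
  d0 <- dev[i]
  d1 <- dev[i + 1L]
  if (!is.finite(d0) || !is.finite(d1) || d1 == d0) {
    return(t[i + 1L])
  }
  t[i] + (level - d0) / (d1 - d0) * (t[i + 1L] - t[i])
}

ts_check <- function(values, fs, what = "signal") {
  if (!is.numeric(values) || length(values) < 2L) {
    abort(sprintf("%s must be a numeric vector of length >= 2", what))
  }
  if (!all(is.finite(values))) {
    abort(sprintf("%s contains non-finite values", what))
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort(sprintf("sampling rate for %s must be a single positive number", what))
  }
  invisible(TRUE)
}

# Extract a numeric column from a data frame, accepting either a bare tibble
# column name (string) or a plain numeric vector.
pull_signal <- function(x, col = "value") {
  if (is.data.frame(x)) {
    if (!col %in% names(x)) {
      abort(sprintf("column '%s' not found in the supplied data frame", col))
    }
    as.numeric(x[[col]])
  } else {
    as.numeric(x)
  }
}

# Sampling rate of a time-series tibble: the `fs` attribute if present,
# otherwise inferred from the median spacing of column `t`.
signal_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) {
    return(fs)
  }
  a <- attr(x, "fs")
  if (!is.null(a)) {
    return(a)
  }
  if (is.data.frame(x) && "t" %in% names(x) && nrow(x) >= 2L) {
    dt <- median(diff(x$t))
    if (is.finite(dt) && dt > 0) {
      return(1 / dt)
    }
  }
  abort("could not determine the sampling rate; pass `fs` explicitly")
}

new_signal_tbl <- function(values, fs, t0 = 0, value_name = "value") {
  out <- tibble(
    t = t0 + (seq_along(values) - 1L) / fs,
    !!value_name := as.numeric(values)
  )
  attr(out, "fs") <- fs
  out
}
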