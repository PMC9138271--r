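# Independent brute-force oracles, kept deliberately naive: explicit loops and
# direct sums, no shared code with the package internals they check.

# Loop-based modulation index: histogram loop, direct entropy sum.
naive_mi <- function(phase, amplitude, n_bins = 20) {
  width <- 360 / n_bins
  sums <- numeric(n_bins)
  counts <- integer(n_bins)
  for (i in seq_along(phase)) {
    j <- floor((phase[i] + 180) / width) + 1
    if (j > n_bins) j <- n_bins
    sums[j] <- sums[j] + amplitude[i]
    counts[j] <- counts[j] + 1
  }
  means <- numeric(n_bins)
  for (j in seq_len(n_bins)) {
    if (counts[j] > 0) means[j] <- sums[j] / counts[j]
  }
  p <- means / sum(means)
  h <- 0
  for (j in seq_len(n_bins)) {
    if (p[j] > 0) h <- h - p[j] * log(p[j])
  }
  (log(n_bins) - h) / log(n_bins)
}

# Naive analytic-signal phase/amplitude via direct DFT manipulation is the
# package's own primitive; the oracle equivalence check therefore feeds the
# SAME phase/amplitude series to both MI routes and compares the binning and
# index arithmetic, which is where the equations live.

# Power in a frequency band from the raw periodogram.
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sum(sp[freqs >= f_lo & freqs <= f_hi & freqs <= fs / 2])
}

# Closed-form bin distribution for amplitude = 1 + cos(phase) under dense
# uniform phase: bin average of (1 + cos) by numerical integration.
cosine_bin_distribution <- function(n_bins = 20) {
  width <- 2 * pi / n_bins
  lo <- -pi + (seq_len(n_bins) - 1) * width
  p <- vapply(lo, function(a) {
    stats::integrate(function(th) 1 + cos(th), a, a + width)$value
  }, numeric(1))
  p / sum(p)
}

expect_distribution <- function(p) {
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
}

# Zero-phase 4th-order Butterworth band-pass, for building test signals.
butter_bandpass <- function(x, fs, lo, hi) {
  b <- signal::butter(4, c(lo, hi) / (fs / 2), "pass")
  signal::filtfilt(b, x)
}
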