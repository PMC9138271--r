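tone_recording <- function(freqs, amps, fs, dur = 10, dc = 0) {
  t <- (0:(fs * dur - 1)) / fs
  x <- dc + rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  recording(list(`C3-M1` = x, `C4-M2` = x), fs = fs)
}

test_that("anti-alias filtering attenuates out-of-band tones and removes DC", {
  fs <- 400
  rec <- tone_recording(c(10, 120), c(1, 1), fs)
  out <- antialias_and_detrend(rec)
  x <- out$channels$`C3-M1`
  # a 4th-order Butterworth at 1.2x cutoff gives |H| ~ 0.27 per pass; the
  # zero-phase double pass squares it, ~23 dB in power
  atten_db <- 10 * log10(band_power(rec$channels$`C3-M1`, fs, 119, 121) /
                           band_power(x, fs, 119, 121))
  expect_gt(atten_db, 20)

  rec_dc <- tone_recording(10, 1, fs, dc = 50)
  expect_lt(abs(mean(antialias_and_detrend(rec_dc)$channels$`C3-M1`)), 0.1)

  # 10 Hz passband tone preserved within 1% (amplitude via interior RMS)
  core <- (fs * 2):(fs * 8)
  a_in <- sqrt(2 * mean(rec_dc$channels$`C3-M1`[core]^2 -
                          mean(rec_dc$channels$`C3-M1`[core])^2))
  out10 <- antialias_and_detrend(rec_dc)$channels$`C3-M1`
  a_out <- sqrt(2 * mean(out10[core]^2))
  expect_equal(a_out, a_in, tolerance = 0.01)

  expect_error(antialias_and_detrend(recording(list(`C3-M1` = 1:10), fs = 1)),
               "too low")
})

test_that("band splitting isolates tones, caps gamma below Nyquist and is linear", {
  fs <- 200
  rec <- tone_recording(5.5, 1, fs)
  dec <- split_bands(rec)
  expect_named(dec$`C3-M1`, c("vlf", "delta", "theta", "alpha", "beta", "gamma"))
  core <- (fs * 2):(fs * 8)
  amp_theta <- sqrt(2 * mean(dec$`C3-M1`$theta[core]^2))
  amp_alpha <- sqrt(2 * mean(dec$`C3-M1`$alpha[core]^2))
  expect_gt(amp_theta, 0.95)
  expect_lt(amp_alpha, 0.10)

  bands <- attr(dec, "bands")
  expect_equal(bands$f_high[bands$name == "gamma"], 99)

  # bands are not a partition: stop-band energy is discarded
  set.seed(1)
  noise <- recording(list(`C3-M1` = stats::rnorm(fs * 10),
                          `C4-M2` = stats::rnorm(fs * 10)), fs = fs)
  decn <- split_bands(noise)
  tot <- sum(noise$channels$`C3-M1`^2)
  parts <- sum(vapply(decn$`C3-M1`, function(b) sum(b^2), numeric(1)))
  expect_lt(parts, tot)

  # linearity
  rec2 <- recording(lapply(rec$channels, `*`, 3), fs = fs)
  dec2 <- split_bands(rec2)
  expect_equal(dec2$`C3-M1`$theta, 3 * dec$`C3-M1`$theta, tolerance = 1e-10)

  expect_error(split_bands(rec, bands = data.frame(name = "bad", f_low = 100,
                                                   f_high = 120)),
               "Nyquist")
})

test_that("band filters are zero-phase at the band's centre tone", {
  fs <- 200
  t <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * 5.5 * t)
  rec <- recording(list(`C3-M1` = x, `C4-M2` = x), fs = fs)
  y <- split_bands(rec)$`C3-M1`$theta
  core <- (fs * 2):(fs * 8)
  cc <- stats::ccf(x[core], y[core], lag.max = 20, plot = FALSE)
  expect_identical(cc$lag[which.max(cc$acf)], 0)
})

test_that("FastICA separates independent sources and is seed-deterministic", {
  set.seed(4)
  n <- 4000
  s1 <- sin(2 * pi * 7 * (1:n) / 200)
  s2 <- sign(sin(2 * pi * 1.1 * (1:n) / 200))   # non-Gaussian square source
  x <- rbind(0.7 * s1 + 0.3 * s2, 0.4 * s1 - 0.6 * s2)
  ica <- fast_ica(x, seed = 10)
  cors <- abs(stats::cor(t(ica$S), cbind(s1, s2)))
  expect_gt(max(cors[, 1]), 0.95)
  expect_gt(max(cors[, 2]), 0.95)
  ica2 <- fast_ica(x, seed = 10)
  expect_identical(ica$S, ica2$S)
})

test_that("artifact-component removal is a near no-op on clean EEG and removes line noise", {
  hyp <- hypnogram(rep("N2", 4))
  rec <- generate_coupled_eeg(hyp, list(flat_profile("theta-gamma", 0.5)),
                              seed = 6)
  clean <- remove_artifact_components(rec, seed = 2)
  expect_identical(sum(clean$report$removed), 0L)
  for (ch in names(rec$channels)) {
    expect_gt(stats::cor(clean$recording$channels[[ch]],
                         rec$channels[[ch]]), 0.99)
  }

  noisy <- inject_artifacts(rec, "line_noise", seed = 3)
  fixed <- remove_artifact_components(noisy$recording, seed = 2)
  expect_true(any(grepl("line", fixed$report$rule)))
  for (ch in names(rec$channels)) {
    red_db <- 10 * log10(
      band_power(noisy$recording$channels[[ch]], 200, 49, 51) /
        band_power(fixed$recording$channels[[ch]], 200, 49, 51))
    expect_gt(red_db, 10)
  }
  fixed2 <- remove_artifact_components(noisy$recording, seed = 2)
  expect_identical(fixed$report, fixed2$report)

  expect_error(remove_artifact_components(
    recording(list(`C3-M1` = stats::rnorm(400)), fs = 200)), "2 channels")
})
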