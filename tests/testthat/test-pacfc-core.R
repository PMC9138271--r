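test_that("modulation index and KL/entropy identities hold on canonical distributions", {
  unif <- rep(1 / 20, 20)
  dirac <- c(1, rep(0, 19))
  half <- c(0.5, 0.5, rep(0, 18))

  expect_identical(modulation_index(unif), 0)
  expect_identical(modulation_index(dirac), 1)
  expect_equal(modulation_index(half), 1 - log(2) / log(20), tolerance = 1e-12)

  expect_identical(kl_distance(unif, unif), 0)
  expect_equal(kl_distance(dirac, unif), log(20), tolerance = 1e-12)
  expect_equal(kl_distance(half, unif), log(20) - log(2), tolerance = 1e-12)
  expect_error(kl_distance(dirac, c(0, rep(1 / 19, 19))), "infinite")

  expect_equal(shannon_entropy(unif), log(20), tolerance = 1e-12)
  expect_identical(shannon_entropy(dirac), 0)
  expect_equal(shannon_entropy(half), log(2), tolerance = 1e-12)

  expect_error(modulation_index(1), "fewer than 2")
  expect_error(kl_distance(c(0.4, 0.4), unif), "sum to 1")
})

test_that("KL distance is non-negative and MI decreases with entropy over random draws", {
  set.seed(42)
  for (i in 1:200) {
    p <- stats::rgamma(20, 1); p <- p / sum(p)
    q <- stats::rgamma(20, 1); q <- q / sum(q)
    expect_gte(kl_distance(p, q), 0)
    mi <- modulation_index(p)
    expect_gte(mi, 0); expect_lte(mi, 1)
    expect_equal(mi, (log(20) - shannon_entropy(p)) / log(20), tolerance = 1e-12)
  }
})

test_that("analytic phase advances linearly for a cosine and envelopes are flat for tones", {
  fs <- 200
  t <- (0:(fs * 4 - 1)) / fs
  ha <- hilbert_phase_amplitude(cos(2 * pi * 2 * t), sin(2 * pi * 60 * t))
  expect_true(all(ha$phase >= -180 & ha$phase < 180))
  expect_true(all(ha$amplitude >= 0))

  # unwrap and regress: a 2 Hz cosine's phase advances 720 degrees per second
  dp <- diff(ha$phase)
  dp[dp < -180] <- dp[dp < -180] + 360
  unwrapped <- cumsum(c(ha$phase[1], dp))
  core <- seq(fs, length(t) - fs)   # stay clear of FFT edge effects
  slope <- stats::coef(stats::lm(unwrapped[core] ~ t[core]))[2]
  expect_equal(unname(slope), 720, tolerance = 0.01)

  env <- ha$amplitude[core]
  expect_lt(stats::sd(env) / mean(env), 0.02)

  expect_error(hilbert_phase_amplitude(1:3, 1:3), "short")
  expect_error(hilbert_phase_amplitude(1:10, 1:9), "equal length")
})

test_that("phase binning reproduces closed-form distributions", {
  set.seed(7)
  ph <- stats::runif(20000, -180, 180)

  d <- bin_mean_amplitude(ph, rep(3.5, length(ph)))
  expect_distribution(d$p)
  expect_equal(d$p, rep(1 / 20, 20), tolerance = 1e-12)
  expect_equal(diff(d$edges)[1], 18)
  expect_length(d$edges, 21)

  d2 <- bin_mean_amplitude(rep(-171, 100), stats::runif(100))
  expect_equal(d2$p[1], 1)
  expect_equal(sum(d2$p[-1]), 0)

  # dense midpoint phase grid makes the bin means match the integral oracle
  # to second order in the grid step
  ph_dense <- seq(-180 + 0.009, 180 - 0.009, by = 0.018)
  amp <- 1 + cos(ph_dense * pi / 180)
  d3 <- bin_mean_amplitude(ph_dense, amp)
  expect_equal(d3$p, cosine_bin_distribution(20), tolerance = 1e-6)

  # phases confined to half the circle: empty bins get zero mass, P stays
  # a distribution
  d4 <- bin_mean_amplitude(stats::runif(5000, 0, 180), rep(1, 5000))
  expect_distribution(d4$p)
  expect_true(all(d4$p[1:10] == 0))
})

test_that("windowed MI slices agree with independent single-shot computation", {
  fs <- 200
  set.seed(11)
  lo <- butter_bandpass(stats::rnorm(fs * 30), fs, 4, 7)
  hi <- butter_bandpass(stats::rnorm(fs * 30), fs, 31, 99)

  w <- windowed_mi(lo, hi, fs)
  expect_identical(nrow(w), 11L)            # floor((30-5)/2.5)+1
  expect_identical(nrow(windowed_mi(lo[1:(5 * fs)], hi[1:(5 * fs)], fs)), 1L)
  expect_error(windowed_mi(lo, hi, fs, overlap = 1), "overlap")

  for (k in seq_len(nrow(w))) {
    idx <- (w$start[k] * fs + 1):(w$end[k] * fs)
    ha <- hilbert_phase_amplitude(lo[idx], hi[idx])
    expect_equal(w$mi[k], naive_mi(ha$phase, ha$amplitude), tolerance = 1e-10)
  }
})

test_that("stage aggregation assigns windows by start epoch and drops stage-spanning windows", {
  fs <- 200
  hyp <- hypnogram(c("N2", "N2", "REM", "REM"))
  profs <- list(flat_profile("theta-gamma", 0.5))
  rec <- generate_coupled_eeg(hyp, profs, seed = 3)
  dec <- split_bands(rec, bands = theta_gamma_bands())
  sm <- stage_mi(dec, hyp, pairs = default_pairs()["theta-gamma"])

  expect_setequal(sm$stage, c("N2", "REM"))
  # 120 s -> 47 windows/channel; the one starting at 57.5 s spans the
  # 60 s stage change: 1 discarded per channel
  expect_identical(unique(sm$n_discarded), 2L)
  expect_identical(sum(sm$n_windows), 2L * 47L - 2L)

  single <- stage_mi(dec, hypnogram(rep("N3", 4)),
                     pairs = default_pairs()["theta-gamma"])
  expect_identical(nrow(single), 1L)
  expect_identical(single$stage, "N3")
  expect_error(stage_mi(dec, hyp), "delta-alpha")
})
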