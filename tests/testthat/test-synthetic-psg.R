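test_that("hypnogram generation respects epoch arithmetic and the transition model", {
  expect_length(generate_hypnogram(8, seed = 1)$stages, 960)

  pinned <- diag(5)[match("N2", c("W", "N1", "N2", "N3", "REM")), , drop = FALSE]
  P <- matrix(rep(pinned, 5), 5, byrow = TRUE,
              dimnames = list(c("W", "N1", "N2", "N3", "REM"),
                              c("W", "N1", "N2", "N3", "REM")))
  hyp <- generate_hypnogram(1, seed = 1, transition = P)
  expect_identical(unique(hyp$stages[-1]), "N2")   # absorbing after the W start

  bad <- default_transition_matrix(); bad[1, 1] <- 0.5
  expect_error(generate_hypnogram(1, transition = bad), "sum to 1")
})

test_that("long-run stage proportions match the transition matrix's stationary vector", {
  P <- default_transition_matrix()
  pi_inf <- stationary_distribution(P)
  # pool enough nights that the autocorrelated chain's occupancy estimates
  # converge (epoch dwell times are ~5-15 epochs, shrinking the effective n)
  stages <- unlist(lapply(1:30, function(night) {
    generate_hypnogram(8, seed = 300 + night)$stages
  }))
  emp <- table(factor(stages, names(pi_inf))) / length(stages)
  for (s in names(pi_inf)) {
    expect_lt(abs(emp[[s]] - pi_inf[[s]]), pmax(0.1 * pi_inf[[s]], 0.02))
  }
})

test_that("coupled EEG realizes the requested modulation depth", {
  hyp <- hypnogram(rep("N2", 2))
  # no coupling: MI stays below the finite-sample bias bound
  rec0 <- generate_coupled_eeg(hyp, list(flat_profile("theta-gamma", 0)),
                               seed = 21)
  dec0 <- split_bands(rec0, bands = theta_gamma_bands())
  w0 <- windowed_mi(dec0$`C3-M1`$theta, dec0$`C3-M1`$gamma, 200)
  expect_lt(mean(w0$mi), 0.02)

  # full coupling, no noise: MI matches the analytic 1 + cos bin distribution
  rec1 <- generate_coupled_eeg(hyp, list(flat_profile("theta-gamma", 1)),
                               seed = 21, noise_sd = 0)
  dec1 <- split_bands(rec1, bands = theta_gamma_bands())
  w1 <- windowed_mi(dec1$`C3-M1`$theta, dec1$`C3-M1`$gamma, 200)
  mi_analytic <- modulation_index(cosine_bin_distribution(20))
  expect_equal(mean(w1$mi), mi_analytic, tolerance = 0.05)

  rec1b <- generate_coupled_eeg(hyp, list(flat_profile("theta-gamma", 1)),
                                seed = 21, noise_sd = 0)
  expect_identical(rec1$channels, rec1b$channels)

  expect_error(generate_coupled_eeg(hyp, list(flat_profile("theta-gamma", 1)),
                                    fs = 100), "twice the highest")
})

test_that("artifact injection is inert for empty kinds and logged otherwise", {
  hyp <- hypnogram(rep("N2", 2))
  rec <- generate_coupled_eeg(hyp, list(flat_profile("theta-gamma", 0.3)),
                              seed = 5)
  none <- inject_artifacts(rec, character(0), seed = 1)
  expect_identical(none$recording$channels, rec$channels)
  expect_identical(nrow(none$log), 0L)
  expect_error(inject_artifacts(rec, "tv_static"), "unknown artifact")

  line <- inject_artifacts(rec, "line_noise", seed = 1)
  x <- line$recording$channels$`C3-M1`
  p50 <- band_power(x, 200, 49, 51)
  expect_gt(p50, band_power(x, 200, 44, 46))
  expect_gt(p50, band_power(x, 200, 54, 56))

  blinks <- inject_artifacts(rec, "eye_blink", seed = 2, n_events = 7)
  expect_identical(sum(blinks$log$kind == "eye_blink"), 7L)
})

test_that("respiratory generator plants the requested event load with valid evidence", {
  hyp <- generate_hypnogram(6.3, seed = 4)
  expect_error(generate_respiratory_and_ecg(hyp, -1), "non-negative")

  none <- generate_respiratory_and_ecg(hyp, 0, seed = 1)
  expect_identical(nrow(none$events), 0L)

  rb <- generate_respiratory_and_ecg(hyp, 30, seed = 1)
  lambda <- 30 * sleep_hours(hyp)
  expect_gte(nrow(rb$events), stats::qpois(0.005, lambda))
  expect_lte(nrow(rb$events), stats::qpois(0.995, lambda))

  hypop <- rb$events[rb$events$type == "hypopnea", ]
  expect_true(all(hypop$evidence %in% c("desaturation", "arousal")))
  expect_true(all(rb$events$duration >= 10 & rb$events$duration <= 40))
  expect_true(all(rb$events$drop[rb$events$type == "apnea"] >= 0.90))

  # every logged event overlaps a real excursion drop of its class
  for (i in seq_len(nrow(rb$events))) {
    idx <- round(rb$events$onset[i] * rb$fs_air) +
      seq_len(round(rb$events$duration[i] * rb$fs_air))
    seg_amp <- max(abs(rb$airflow[idx]))
    expect_lt(seg_amp, 1 - rb$events$drop[i] + 0.05)
  }
})

test_that("cohort generation matches the configured sizes, groups and depth directions", {
  spec <- cohort_spec(n_low = 4, n_high = 5, night_min = 2.5, seed = 8)
  cohort <- generate_cohort(spec)
  expect_identical(nrow(cohort$subjects), 9L)
  expect_identical(sum(cohort$subjects$rdi <= 15), 4L)
  expect_true(all(cohort$subjects$group ==
                    assign_group(cohort$subjects$rdi)))
  expect_true(all(cohort$subjects$ess >= 0 & cohort$subjects$ess <= 24))

  # deterministic under the seed
  cohort2 <- generate_cohort(spec)
  expect_identical(cohort$subjects, cohort2$subjects)
  expect_identical(cohort$recordings[[1]]$channels,
                   cohort2$recordings[[1]]$channels)

  # configured directions hold for the group-mean true depths
  gt <- cohort$ground_truth$depths
  low_ids <- cohort$subjects$id[cohort$subjects$rdi <= 15]
  high_ids <- setdiff(cohort$subjects$id, low_ids)
  mean_depth <- function(ids, pair, stage) {
    mean(vapply(ids, function(id) gt[[id]][[pair]][[stage]], numeric(1)))
  }
  for (st in c("W", "N1", "N2", "N3", "REM")) {
    expect_gt(mean_depth(low_ids, "theta-gamma", st),
              mean_depth(high_ids, "theta-gamma", st))
  }
  expect_gt(mean_depth(low_ids, "delta-alpha", "REM"),
            mean_depth(high_ids, "delta-alpha", "REM"))
  expect_lt(mean_depth(low_ids, "delta-alpha", "N2"),
            mean_depth(high_ids, "delta-alpha", "N2"))
})

test_that("equal group coupling yields non-significant downstream group tests", {
  eq_depths <- list(low = group_depth_profiles()$low,
                    high = group_depth_profiles()$low)
  sig <- vapply(1:20, function(r) {
    cohort <- generate_cohort(cohort_spec(n_low = 4, n_high = 4,
                                          night_min = 2.5, seed = 5000 + r),
                              depths = eq_depths)
    mi_n2 <- vapply(cohort$subjects$id, function(id) {
      dec <- split_bands(cohort$recordings[[id]], bands = theta_gamma_bands())
      sm <- stage_mi(dec, cohort$hypnograms[[id]],
                     pairs = default_pairs()["theta-gamma"])
      sm$mi[sm$stage == "N2"]
    }, numeric(1))
    low <- cohort$subjects$rdi <= 15
    compare_groups(mi_n2[low], mi_n2[!low])$p < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)
})

test_that("a written cohort round-trips through the on-disk formats", {
  spec <- cohort_spec(n_low = 1, n_high = 1, night_min = 2.5, seed = 3,
                      target_rdi_signals = TRUE)
  cohort <- generate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "S001.edf", "S001_hypnogram.csv", "S002.edf", "subjects.csv",
    "ground_truth.json")))))
  psg <- read_psg(file.path(dir, "S001.edf"))
  expect_true(all(c("Airflow", "SpO2", "RR") %in% names(psg$recording$channels)))
  meta <- utils::read.csv(file.path(dir, "subjects.csv"))
  expect_identical(nrow(meta), 2L)
})
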