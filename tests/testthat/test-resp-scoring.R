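sine_airflow <- function(total_s, fs = 10, breath_hz = 0.25, events = NULL) {
  t <- (0:(total_s * fs - 1)) / fs
  A <- rep(1, length(t))
  if (!is.null(events)) {
    for (i in seq_len(nrow(events))) {
      idx <- t >= events$onset[i] & t < events$onset[i] + events$duration[i]
      A[idx] <- 1 - events$drop[i]
    }
  }
  A * sin(2 * pi * breath_hz * t)
}

test_that("excursion envelope tracks breath amplitude and the baseline is median-robust", {
  af <- sine_airflow(400)
  ee <- excursion_envelope(af, 10)
  core <- 50:3950
  expect_lt(stats::sd(ee$envelope[core]) / mean(ee$envelope[core]), 0.02)

  # amplitude halved for 20 s: envelope shows ~0.5 relative drop
  af2 <- sine_airflow(400, events = data.frame(onset = 200, duration = 20,
                                               drop = 0.5))
  ee2 <- excursion_envelope(af2, 10)
  mid <- round(210 * 10)
  expect_equal(ee2$envelope[mid] / ee2$baseline[mid], 0.5, tolerance = 0.05)

  # 12-s total dropout barely moves the 100-s median baseline
  af3 <- sine_airflow(400, events = data.frame(onset = 200, duration = 12,
                                               drop = 1))
  ee3 <- excursion_envelope(af3, 10)
  expect_equal(ee3$baseline[260 * 10] / ee3$baseline[150 * 10], 1,
               tolerance = 0.05)

  expect_error(excursion_envelope(af[1:500], 10), "baseline window")
})

test_that("event rules score the constructed boundary cases exactly", {
  hyp <- hypnogram(rep("N2", 14))   # 420 s, asleep throughout
  # 12 s at 95% -> one apnea; 8 s at 95% -> nothing
  for (cfg in list(list(d = 12, n = 1, type = "apnea"),
                   list(d = 8, n = 0, type = NULL))) {
    af <- sine_airflow(420, events = data.frame(onset = 200, duration = cfg$d,
                                                drop = 0.95))
    ev <- score_events(af, 10, spo2 = rep(97, 420), fs_spo2 = 1,
                       arousals = NULL, hyp = hyp)
    expect_identical(nrow(ev), as.integer(cfg$n))
    if (cfg$n > 0) expect_identical(ev$type, cfg$type)
  }

  # 15 s at 40% with a 4% desaturation -> hypopnea; without evidence -> nothing
  af <- sine_airflow(420, events = data.frame(onset = 200, duration = 15,
                                              drop = 0.40))
  spo2 <- rep(97, 420); spo2[221:239] <- 93
  with_desat <- score_events(af, 10, spo2, 1, NULL, hyp)
  expect_identical(with_desat$type, "hypopnea")
  expect_identical(with_desat$evidence, "desaturation")
  no_evidence <- suppressWarnings(score_events(af, 10, NULL, 1, NULL, hyp))
  expect_identical(nrow(no_evidence), 0L)

  # arousal marker is accepted as the alternative evidence
  with_arousal <- score_events(af, 10, NULL, 1, arousals = 218, hyp = hyp)
  expect_identical(with_arousal$evidence, "arousal")

  # events during wake are discarded
  hyp_w <- hypnogram(rep("W", 14))
  ev_w <- score_events(af, 10, spo2, 1, NULL, hyp_w)
  expect_identical(nrow(ev_w), 0L)
})

test_that("planted synthetic events are recovered exactly on clean airflow", {
  hyp <- generate_hypnogram(6, seed = 3)
  rb <- generate_respiratory_and_ecg(hyp, 10, seed = 7)
  ev <- score_events(rb$airflow, rb$fs_air, rb$spo2, rb$fs_spo2, rb$arousals,
                     hyp)
  truth <- rb$events

  # sensitivity and precision both 1: every planted event matched, no extras
  matched <- vapply(truth$onset,
                    function(o) any(abs(ev$onset - o) < 5), logical(1))
  expect_identical(sum(matched), nrow(truth))
  expect_identical(nrow(ev), nrow(truth))
  # classes agree
  nearest <- vapply(truth$onset,
                    function(o) which.min(abs(ev$onset - o)), integer(1))
  expect_identical(ev$type[nearest], truth$type)
  # scored events never overlap
  ord <- order(ev$onset)
  expect_true(all(diff(ev$onset[ord]) >= ev$duration[ord][-nrow(ev)]))

  # clean airflow without events scores nothing
  quiet <- generate_respiratory_and_ecg(hyp, 0, seed = 8)
  ev0 <- score_events(quiet$airflow, quiet$fs_air, quiet$spo2, quiet$fs_spo2,
                      quiet$arousals, hyp)
  expect_identical(nrow(ev0), 0L)
})

test_that("RDI arithmetic divides events by non-wake hours", {
  hyp <- hypnogram(rep(c("W", "N2", "N2", "N2"), 180))   # 6 h sleep of 8 h
  ev <- data.frame(onset = seq_len(30), duration = 12)
  r <- compute_rdi(ev, hyp)
  expect_identical(r$n_events, 30L)
  expect_equal(r$sleep_hours, 4.5)
  expect_equal(r$rdi, 30 / 4.5)
  expect_equal(compute_rdi(ev[0, ], hyp)$rdi, 0)
  expect_error(compute_rdi(ev, hypnogram(rep("W", 10))), "zero sleep")
})
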