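#' Default sleep-stage transition matrix
#'
#' First-order Markov transition matrix over 30-s epochs (rows sum to 1),
#' tuned so the stationary occupancy approximates typical adult sleep
#' architecture: about 5% W, 10% N1, 51% N2, 14% N3, 20% REM.
#'
#' @return 5x5 row-stochastic matrix with W/N1/N2/N3/REM dimnames.
#' @export
default_transition_matrix <- function() {
  P <- rbind(
    W   = c(.760, .180, .030, .000, .030),
    N1  = c(.040, .720, .210, .000, .030),
    N2  = c(.008, .022, .938, .017, .015),
    N3  = c(.008, .004, .048, .940, .000),
    REM = c(.015, .030, .015, .000, .940))
  colnames(P) <- rownames(P)
  P
}

#' Stationary distribution of a stage transition matrix
#' @param P Row-stochastic matrix.
#' @return Named probability vector (left eigenvector for eigenvalue 1).
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  stats::setNames(v / sum(v), rownames(P))
}

#' Simulate a night's hypnogram
#'
#' First-order Markov chain over 30-s epochs starting in W (lights off).
#'
#' @param duration_h Night length in hours (> 0).
#' @param seed Integer seed.
#' @param transition Row-stochastic 5x5 matrix (rows/cols W,N1,N2,N3,REM).
#' @param epoch_s Epoch length, seconds.
#' @return A `hypnogram` with `duration_h * 3600 / epoch_s` epochs.
#' @export
generate_hypnogram <- function(duration_h, seed = 1,
                               transition = default_transition_matrix(),
                               epoch_s = 30) {
  if (duration_h <= 0) stop("duration must be positive")
  if (any(abs(rowSums(transition) - 1) > 1e-8)) {
    stop("transition matrix rows must sum to 1")
  }
  n <- floor(duration_h * 3600 / epoch_s)
  set.seed(seed)
  stages <- character(n)
  cur <- "W"
  for (i in seq_len(n)) {
    stages[i] <- cur
    cur <- sample(colnames(transition), 1, prob = transition[cur, ])
  }
  hypnogram(stages, epoch_s = epoch_s)
}

#' Coupling profile for one band pair
#'
#' Per-stage phase-amplitude coupling depth m in \[0, 1\]: the fractional
#' amplitude modulation of the fast oscillation by the slow oscillation's
#' phase.
#'
#' @param band_pair `"theta-gamma"` or `"delta-alpha"` (any label in
#'   [default_pairs()] style works if frequencies are supplied).
#' @param depths Named numeric vector with entries for W, N1, N2, N3, REM,
#'   each in \[0, 1\].
#' @param f_low,f_high Carrier frequencies (Hz) inside the phase and amplitude
#'   bands; defaults 5.5/60 for theta-gamma and 2/10 for delta-alpha.
#' @param a_low,a_high Carrier amplitudes, microvolts.
#' @return An object of class `coupling_profile`.
#' @export
coupling_profile <- function(band_pair, depths,
                             f_low = NULL, f_high = NULL,
                             a_low = NULL, a_high = NULL) {
  if (!all(SLEEP_STAGES %in% names(depths))) {
    stop("depths must name all five stages W,N1,N2,N3,REM")
  }
  if (any(depths < 0 | depths > 1)) stop("coupling depths must be in [0,1]")
  defaults <- list(
    "theta-gamma" = list(f_low = 5.5, f_high = 60, a_low = 18, a_high = 13),
    "delta-alpha" = list(f_low = 2.0, f_high = 10, a_low = 25, a_high = 8.2))
  d <- defaults[[band_pair]]
  if (is.null(d)) d <- list(f_low = NA, f_high = NA, a_low = 1, a_high = 1)
  structure(list(band_pair = band_pair,
                 depths = depths[SLEEP_STAGES],
                 f_low = f_low %||% d$f_low, f_high = f_high %||% d$f_high,
                 a_low = a_low %||% d$a_low, a_high = a_high %||% d$a_high),
            class = "coupling_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' 1/f (pink) background noise
#'
#' Spectral synthesis: Fourier amplitudes proportional to `1/sqrt(f)` with
#' uniform random phases, normalized to unit standard deviation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate, Hz.
#' @return Numeric vector with `sd(x) == 1`.
#' @keywords internal
pink_noise <- function(n, fs) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = 1 / sqrt(f), argument = ph)
  full <- c(0, spec,
            if (n %% 2 == 0) Conj(rev(spec[-nf])) else Conj(rev(spec)))
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}

#' Synthesize stage-dependent phase-amplitude-coupled EEG
#'
#' For each band pair the fast carrier's amplitude is multiplicatively
#' modulated by the slow carrier's instantaneous phase:
#' `a_high * [1 + m_s cos(phi_low(t))] * sin(2 pi f_high t)`, with the
#' stage-dependent depth `m_s` taken per sample from the hypnogram. The slow
#' carrier itself and 1/f background noise are added; the two channels share
#' the oscillatory content but receive independent noise. Carrier amplitudes
#' default to a band-filtered signal-to-noise ratio of about 3 for the
#' amplitude bands (6 for the phase bands) at `noise_sd = 10` microvolts.
#'
#' @param hyp A `hypnogram`.
#' @param profiles List of `coupling_profile`s.
#' @param fs Sampling rate, Hz (must exceed twice the highest carrier).
#' @param seed Integer seed.
#' @param noise_sd Pink-noise standard deviation, microvolts.
#' @param channels Channel labels for the two EEG derivations.
#' @return A `psg_recording` with the two EEG channels.
#' @export
generate_coupled_eeg <- function(hyp, profiles, fs = 200, seed = 1,
                                 noise_sd = 10,
                                 channels = c("C3-M1", "C4-M2")) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (length(hyp$stages) == 0) stop("empty hypnogram")
  fmax <- max(vapply(profiles, function(p) max(p$f_low, p$f_high), 0))
  if (fs < 2 * fmax) stop("sampling rate below twice the highest carrier")
  n <- length(hyp$stages) * hyp$epoch_s * fs
  t <- (0:(n - 1)) / fs
  stage_of_sample <- rep(hyp$stages, each = hyp$epoch_s * fs)
  base <- numeric(n)
  for (p in profiles) {
    m <- unname(p$depths[stage_of_sample])
    slow <- sin(2 * pi * p$f_low * t)       # cos of the slow carrier's phase
    base <- base +
      p$a_high * (1 + m * slow) * sin(2 * pi * p$f_high * t) +
      p$a_low * slow
  }
  set.seed(seed)
  chans <- lapply(seq_along(channels), function(i) {
    base + noise_sd * if (noise_sd > 0) pink_noise(n, fs) else 0
  })
  names(chans) <- channels
  recording(chans, fs = fs)
}

#' Inject stereotyped EEG artifacts
#'
#' Adds eye-blink transients (300 ms raised-cosine, large amplitude), muscle
#' bursts (band-limited 20 Hz+ noise, ~1 s) and/or continuous 50 Hz line
#' noise to the EEG channels, with channel-specific gains so the artifacts
#' form separable sources. Returns the contaminated recording and a log of
#' what was injected where.
#'
#' @param rec A `psg_recording`.
#' @param kinds Subset of `c("eye_blink", "muscle", "line_noise")`.
#' @param seed Integer seed.
#' @param n_events Transient count per transient kind.
#' @param line_hz Mains frequency (50 Hz, European site).
#' @param eeg_channels EEG channels to contaminate.
#' @return List with `recording` and `log` (data frame kind/onset/duration).
#' @export
inject_artifacts <- function(rec, kinds, seed = 1, n_events = 20,
                             line_hz = 50, eeg_channels = c("C3-M1", "C4-M2")) {
  stopifnot(inherits(rec, "psg_recording"))
  known <- c("eye_blink", "muscle", "line_noise")
  bad <- setdiff(kinds, known)
  if (length(bad)) stop("unknown artifact kind(s): ", paste(bad, collapse = ", "))
  eeg_channels <- intersect(eeg_channels, names(rec$channels))
  if (length(kinds) == 0) {
    return(list(recording = rec,
                log = data.frame(kind = character(), onset = numeric(),
                                 duration = numeric())))
  }
  fs <- unique(rec$fs[eeg_channels])[1]
  n <- length(rec$channels[[eeg_channels[1]]])
  set.seed(seed)
  gains <- stats::setNames(seq(1, 0.5, length.out = length(eeg_channels)),
                           eeg_channels)
  log <- list()
  add <- function(wave, onset_i) {
    idx <- onset_i:(onset_i + length(wave) - 1L)
    idx_ok <- idx <= n
    for (ch in eeg_channels) {
      rec$channels[[ch]][idx[idx_ok]] <<-
        rec$channels[[ch]][idx[idx_ok]] + gains[[ch]] * wave[idx_ok]
    }
  }
  if ("eye_blink" %in% kinds) {
    dur <- round(0.3 * fs)
    wave <- 150 * (1 - cos(2 * pi * seq_len(dur) / dur)) / 2
    onsets <- sort(sample.int(n - dur, n_events))
    for (o in onsets) add(wave, o)
    log$blink <- data.frame(kind = "eye_blink", onset = (onsets - 1) / fs,
                            duration = dur / fs)
  }
  if ("muscle" %in% kinds) {
    dur <- round(1 * fs)
    onsets <- sort(sample.int(n - dur, n_events))
    for (o in onsets) {
      burst <- stats::rnorm(dur)
      burst <- butter_zerophase(burst, fs, "pass", c(20, min(95, 0.95 * fs / 2)))
      add(40 * burst / stats::sd(burst), o)
    }
    log$muscle <- data.frame(kind = "muscle", onset = (onsets - 1) / fs,
                             duration = dur / fs)
  }
  if ("line_noise" %in% kinds) {
    t <- (0:(n - 1)) / fs
    add50 <- 30 * sin(2 * pi * line_hz * t)
    for (ch in eeg_channels) {
      rec$channels[[ch]] <- rec$channels[[ch]] + gains[[ch]] * add50
    }
    log$line <- data.frame(kind = "line_noise", onset = 0, duration = n / fs)
  }
  list(recording = rec, log = do.call(rbind, c(log, make.row.names = FALSE)))
}

#' Synthesize airflow, SpO2, arousal markers and an RR series for a night
#'
#' Plants Poisson-distributed respiratory events (expected count
#' `target_rdi x sleep hours`) inside sleep (non-W) periods: apneas drop the
#' airflow excursion by >= 90% of baseline, hypopneas by 30-89%, durations
#' uniform on \[10, 40\] s. Every hypopnea carries qualifying evidence: a
#' >= 3% SpO2 desaturation lagging the event for a configurable fraction,
#' a cortical-arousal marker for the rest. RR intervals are drawn with a
#' configurable SDNN around 800 ms.
#'
#' @param hyp A `hypnogram`.
#' @param target_rdi Target event rate, events per hour of sleep (>= 0).
#' @param seed Integer seed.
#' @param fs_air,fs_spo2 Sampling rates of airflow and SpO2, Hz.
#' @param breath_hz Respiratory rate, Hz.
#' @param desat_frac Fraction of hypopneas qualified by desaturation (the
#'   remainder get arousal markers).
#' @param sdnn Target SDNN of the RR series, ms.
#' @param min_gap_s Minimum spacing between consecutive events, seconds.
#' @return List with `airflow` (numeric), `spo2` (numeric, %), `arousals`
#'   (marker times, s), `events` (ground-truth log: onset, duration, type,
#'   drop, evidence), `rr` (intervals, ms), `fs_air`, `fs_spo2`.
#' @export
generate_respiratory_and_ecg <- function(hyp, target_rdi, seed = 1,
                                         fs_air = 10, fs_spo2 = 1,
                                         breath_hz = 0.25, desat_frac = 0.6,
                                         sdnn = 50, min_gap_s = 20) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (target_rdi < 0) stop("target RDI must be non-negative")
  set.seed(seed)
  total_s <- length(hyp$stages) * hyp$epoch_s
  sh <- sleep_hours(hyp)
  # contiguous sleep intervals, trimmed so events fit wholly inside sleep
  sleep <- rep(hyp$stages != "W", each = hyp$epoch_s)
  n_target <- if (sh > 0) stats::rpois(1, target_rdi * sh) else 0
  onsets <- durations <- numeric(0)
  types <- character(0)
  if (n_target > 0) {
    cand <- which(sleep)                      # candidate onset seconds
    cand <- cand[cand < total_s - 45]
    tries <- 0
    while (length(onsets) < n_target && tries < 20 * n_target) {
      tries <- tries + 1
      o <- sample(cand, 1)
      d <- stats::runif(1, 10, 40)
      if (o + d > total_s - 2) next
      if (!all(sleep[o:ceiling(o + d)])) next
      if (length(onsets) &&
          any(abs(o - onsets) < min_gap_s + 40)) next
      onsets <- c(onsets, o); durations <- c(durations, d)
      types <- c(types, sample(c("apnea", "hypopnea"), 1))
    }
    ord <- order(onsets)
    onsets <- onsets[ord]; durations <- durations[ord]; types <- types[ord]
  }
  drops <- ifelse(types == "apnea", stats::runif(length(types), 0.92, 1.0),
                  stats::runif(length(types), 0.40, 0.85))
  # airflow: AM sinusoid at the breathing rate
  n_air <- total_s * fs_air
  t_air <- (0:(n_air - 1)) / fs_air
  A <- rep(1, n_air)
  for (i in seq_along(onsets)) {
    idx <- t_air >= onsets[i] & t_air < onsets[i] + durations[i]
    A[idx] <- 1 - drops[i]
  }
  airflow <- A * sin(2 * pi * breath_hz * t_air)

  # evidence: desaturation for a configured fraction of hypopneas (and all
  # apneas, realistically), arousal markers for the remaining hypopneas
  n_spo2 <- total_s * fs_spo2
  t_spo2 <- (0:(n_spo2 - 1)) / fs_spo2
  spo2 <- 97 + stats::rnorm(n_spo2, 0, 0.1)
  arousals <- numeric(0)
  evidence <- character(length(onsets))
  for (i in seq_along(onsets)) {
    is_hyp <- types[i] == "hypopnea"
    desat <- !is_hyp || stats::runif(1) < desat_frac
    if (desat) {
      depth <- stats::runif(1, 3.5, 6)
      start <- onsets[i] + durations[i] + 8
      ramp <- 5; plateau <- 10
      prof <- c(seq(0, depth, length.out = ramp * fs_spo2),
                rep(depth, plateau * fs_spo2),
                seq(depth, 0, length.out = ramp * fs_spo2))
      idx <- round(start * fs_spo2) + seq_along(prof)
      ok <- idx <= n_spo2
      spo2[idx[ok]] <- spo2[idx[ok]] - prof[ok]
      evidence[i] <- "desaturation"
    } else {
      arousals <- c(arousals, onsets[i] + durations[i] + 2)
      evidence[i] <- "arousal"
    }
  }
  # RR intervals spanning the night with the requested SDNN
  n_beats <- ceiling(total_s / 0.8)
  rr <- 800 + stats::rnorm(n_beats, 0, sdnn)
  rr <- pmin(pmax(rr, 300), 2000)

  list(airflow = airflow, spo2 = spo2, arousals = arousals,
       events = data.frame(onset = onsets, duration = durations, type = types,
                           drop = drops, evidence = evidence,
                           stringsAsFactors = FALSE),
       rr = rr, fs_air = fs_air, fs_spo2 = fs_spo2)
}

#' Cohort specification for the synthetic study
#'
#' Defaults emulate the study's main dataset: 42 subjects with RDI <= 15/h
#' (RDI ~ 9.30 +/- 3.26) and 44 with RDI > 15/h (27.96 +/- 12.47); ESS is
#' linked negatively to the subject's mean N2/N3 theta-gamma coupling depth so
#' that both groups land near 11 +/- 4.5 points. Group coupling-depth profiles
#' encode the observed directions: theta-gamma lower in the high-RDI group at
#' every stage, delta-alpha lower at REM and N1, higher at N2, equal at N3.
#'
#' @param n_low,n_high Group sizes.
#' @param rdi_low,rdi_high `c(mean, sd)` of the (truncated) RDI draws.
#' @param ess_intercept,ess_slope,ess_sd ESS link: `ESS = intercept +
#'   slope * mean(m_tg\[N2\], m_tg\[N3\]) + N(0, sd)`, clamped to \[0, 24\].
#' @param depth_sd Between-subject SD of coupling depths around group means.
#' @param night_min Minutes of EEG per subject (balanced stage blocks).
#' @param target_rdi_signals Whether to also synthesize airflow/SpO2/RR.
#' @param seed Master seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_low = 42, n_high = 44,
                        rdi_low = c(9.30, 3.26), rdi_high = c(27.96, 12.47),
                        ess_intercept = 15.5, ess_slope = -8, ess_sd = 4.2,
                        depth_sd = 0.04, night_min = 10,
                        target_rdi_signals = FALSE, seed = 1) {
  if (n_low < 1 || n_high < 1) stop("need at least one subject per group")
  if (any(c(rdi_low, rdi_high)[c(2, 4)] <= 0)) stop("RDI scale must be positive")
  structure(list(n_low = n_low, n_high = n_high, rdi_low = rdi_low,
                 rdi_high = rdi_high, ess_intercept = ess_intercept,
                 ess_slope = ess_slope, ess_sd = ess_sd, depth_sd = depth_sd,
                 night_min = night_min,
                 target_rdi_signals = target_rdi_signals, seed = seed),
            class = "cohort_spec")
}

#' Group-level coupling-depth profiles
#'
#' Stage-by-group coupling depths for both band pairs, encoding the study's
#' qualitative pattern (see [cohort_spec()]).
#'
#' @return Nested list `[[group]][[pair]]` of named depth vectors.
#' @export
group_depth_profiles <- function() {
  list(
    low = list(
      "theta-gamma" = c(W = .35, N1 = .45, N2 = .55, N3 = .60, REM = .40),
      "delta-alpha" = c(W = .30, N1 = .35, N2 = .30, N3 = .40, REM = .40)),
    high = list(
      "theta-gamma" = c(W = .22, N1 = .25, N2 = .47, N3 = .42, REM = .25),
      "delta-alpha" = c(W = .30, N1 = .22, N2 = .42, N3 = .40, REM = .25)))
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

balanced_hypnogram <- function(night_min, epoch_s = 30) {
  per_stage <- max(1L, floor(night_min * 60 / epoch_s / 5))
  hypnogram(rep(SLEEP_STAGES, each = per_stage), epoch_s = epoch_s)
}

#' Generate a synthetic two-group cohort
#'
#' Draws clinical metadata per subject (RDI by group, ESS linked to N2/N3
#' theta-gamma coupling, independent arousal/PLM indices and SDNN), assigns
#' subject-level coupling depths around the group profiles, and synthesizes a
#' coupled-EEG recording per subject over a balanced hypnogram (equal blocks
#' of all five stages, so every stage is observable in a short recording).
#'
#' @param spec A `cohort_spec`.
#' @param depths Group depth profiles as from [group_depth_profiles()].
#' @return List with `subjects` (metadata data frame), `recordings`,
#'   `hypnograms`, `resp` (respiratory bundles or NULL), and `ground_truth`
#'   (per-subject true depths and event logs).
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            depths = group_depth_profiles()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_low + spec$n_high
  grp <- c(rep("low", spec$n_low), rep("high", spec$n_high))
  rdi <- c(rnorm_trunc(spec$n_low, spec$rdi_low[1], spec$rdi_low[2], 0, 15),
           rnorm_trunc(spec$n_high, spec$rdi_high[1], spec$rdi_high[2],
                       15.0001, Inf))
  age <- round(rnorm_trunc(n, 56, 12, 27, 84))
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.35, 0.65))
  arousal_idx <- rnorm_trunc(n, 15, 5, 0, Inf)
  plm_idx <- rnorm_trunc(n, 10, 8, 0, Inf)
  sdnn <- rnorm_trunc(n, 50, 15, 5, Inf)
  # derived per-subject seeds, kept inside the 32-bit integer range
  subj_seed <- (spec$seed %% 2000000) * 1000 + seq_len(n)

  true_depths <- vector("list", n)
  ess <- numeric(n)
  for (i in seq_len(n)) {
    prof <- depths[[grp[i]]]
    td <- lapply(prof, function(d) {
      pmin(pmax(d + stats::rnorm(length(d), 0, spec$depth_sd), 0), 1)
    })
    true_depths[[i]] <- td
    m_n23 <- mean(td[["theta-gamma"]][c("N2", "N3")])
    ess[i] <- round(min(max(
      spec$ess_intercept + spec$ess_slope * m_n23 + stats::rnorm(1, 0, spec$ess_sd),
      0), 24))
  }

  subjects <- data.frame(
    id = sprintf("S%03d", seq_len(n)), age = age, sex = sex,
    ess = ess, rdi = rdi, arousal_index = arousal_idx, plm_index = plm_idx,
    sdnn = sdnn, group = assign_group(rdi), stringsAsFactors = FALSE)

  recordings <- hypnograms <- resp <- vector("list", n)
  events <- vector("list", n)
  for (i in seq_len(n)) {
    hyp <- balanced_hypnogram(spec$night_min)
    profs <- lapply(names(true_depths[[i]]), function(pn) {
      coupling_profile(pn, true_depths[[i]][[pn]])
    })
    recordings[[i]] <- generate_coupled_eeg(hyp, profs, seed = subj_seed[i])
    hypnograms[[i]] <- hyp
    if (spec$target_rdi_signals) {
      resp[[i]] <- generate_respiratory_and_ecg(hyp, target_rdi = rdi[i],
                                                seed = subj_seed[i])
      events[[i]] <- resp[[i]]$events
    }
  }
  names(recordings) <- names(hypnograms) <- subjects$id
  list(subjects = subjects, recordings = recordings, hypnograms = hypnograms,
       resp = if (spec$target_rdi_signals) stats::setNames(resp, subjects$id),
       ground_truth = list(depths = stats::setNames(true_depths, subjects$id),
                           events = stats::setNames(events, subjects$id)))
}

#' Write a generated cohort to disk
#'
#' One EDF per subject (EEG channels, plus airflow/SpO2/RR channels when
#' present), a sidecar hypnogram CSV per subject, a cohort metadata CSV and
#' the ground truth as JSON.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in cohort$subjects$id) {
    rec <- cohort$recordings[[id]]
    if (!is.null(cohort$resp) && !is.null(cohort$resp[[id]])) {
      rb <- cohort$resp[[id]]
      rr_1hz <- stats::approx(cumsum(rb$rr) / 1000, rb$rr,
                              xout = seq(0, duration(rec) - 1), rule = 2)$y
      rec <- recording(
        c(rec$channels, list(Airflow = rb$airflow, SpO2 = rb$spo2, RR = rr_1hz)),
        fs = c(rec$fs, Airflow = rb$fs_air, SpO2 = rb$fs_spo2, RR = 1),
        start_time = rec$start_time)
    }
    write_edf(rec, file.path(dir, paste0(id, ".edf")))
    write_hypnogram_csv(cohort$hypnograms[[id]],
                        file.path(dir, paste0(id, "_hypnogram.csv")))
  }
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
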