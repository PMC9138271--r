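#' Breath-amplitude excursion envelope and rolling baseline
#'
#' The envelope at time t is the peak-to-trough excursion of the airflow
#' signal within a window of `envelope_window_s` centred on t (the window must
#' cover at least one breath cycle). The pre-event baseline is the median
#' envelope over the preceding `baseline_window_s` (default 100 s), evaluated
#' on a 1 s grid and interpolated; the median makes it robust to short
#' dropouts.
#'
#' @param airflow Airflow samples.
#' @param fs Sampling rate, Hz.
#' @param envelope_window_s Excursion window, seconds (>= one breath period).
#' @param baseline_window_s Trailing baseline window, seconds.
#' @return List with `envelope`, `baseline` (same length as `airflow`), `fs`
#'   and `envelope_window_s`.
#' @export
excursion_envelope <- function(airflow, fs, envelope_window_s = 4,
                               baseline_window_s = 100) {
  n <- length(airflow)
  if (n / fs <= baseline_window_s) stop("airflow shorter than baseline window")
  half <- round(envelope_window_s * fs / 2)
  # block prefix/suffix running extremes: O(n) sliding max/min over window w
  run_extreme <- function(x, w, maximum = TRUE) {
    cfun <- if (maximum) cummax else cummin
    nb <- ceiling(length(x) / w)
    pad <- nb * w - length(x)
    xm <- matrix(c(x, rep(x[length(x)], pad)), nrow = w)
    prefix <- apply(xm, 2, cfun)                      # block start .. j
    suffix <- apply(xm[w:1, , drop = FALSE], 2, cfun)[w:1, , drop = FALSE]
    lo <- seq_along(x)
    hi <- pmin(lo + w - 1L, length(x) + pad)
    if (maximum) pmax(suffix[lo], prefix[hi]) else pmin(suffix[lo], prefix[hi])
  }
  w <- 2L * half + 1L
  mx <- run_extreme(airflow, w, TRUE)
  mn <- run_extreme(airflow, w, FALSE)
  # run_extreme gives the extreme over [i, i+w-1]; shift to centre the window
  idx <- pmax(1L, pmin(n, seq_len(n) - half))
  env <- mx[idx] - mn[idx]
  # trailing median baseline on a 1 s grid
  grid <- seq(1, n, by = fs)
  base_grid <- vapply(grid, function(g) {
    lo <- max(1, g - baseline_window_s * fs)
    stats::median(env[lo:g])
  }, numeric(1))
  baseline <- stats::approx(grid, base_grid, xout = seq_len(n), rule = 2)$y
  list(envelope = env, baseline = baseline, fs = fs,
       envelope_window_s = envelope_window_s)
}

refine_run <- function(ratio, lo, hi, fs, w_s) {
  # Duration is measured at a level a quarter of the way from the event's own
  # envelope floor back to baseline. At that level the run excludes the
  # transition zone where the excursion window straddles the event boundary
  # (which sits half-way between floor and baseline for quasi-sinusoidal
  # breathing), so the run underestimates the true duration by exactly one
  # envelope window; adding the window back compensates.
  n <- length(ratio)
  run_min <- min(ratio[lo:hi])
  imin <- lo - 1L + which.min(ratio[lo:hi])
  level <- run_min + 0.25 * (1 - run_min)
  a <- b <- imin
  while (a > 1 && ratio[a - 1] <= level) a <- a - 1
  while (b < n && ratio[b + 1] <= level) b <- b + 1
  core <- (b - a + 1) / fs
  onset <- max((a - 1) / fs - w_s / 2, 0)
  c(onset = onset, duration = core + w_s, run_min = run_min)
}

#' Score apneas and hypopneas from airflow, SpO2 and arousal markers
#'
#' Rule engine for the standard event criteria: an apnea is a drop of the
#' breath-excursion envelope to <= 10% of the rolling pre-event baseline
#' lasting >= 10 s; a hypopnea is a drop to <= 70% of baseline for >= 10 s that
#' is associated (within `evidence_window_s` after the event) with a >= 3%
#' SpO2 desaturation from its pre-event level or with a cortical-arousal
#' marker. Intervals meeting the apnea criterion are scored as apneas only
#' (the more severe class). Events whose onset falls in a W epoch are
#' discarded.
#'
#' @param airflow Airflow samples.
#' @param fs_air Airflow sampling rate, Hz.
#' @param spo2 SpO2 samples (%), or NULL.
#' @param fs_spo2 SpO2 sampling rate, Hz.
#' @param arousals Arousal marker times (s), or NULL.
#' @param hyp A `hypnogram` aligned to the signals.
#' @param min_duration_s Event duration floor, seconds.
#' @param apnea_ratio,hypopnea_ratio Envelope/baseline thresholds.
#' @param desat_drop Desaturation threshold, percentage points.
#' @param evidence_window_s Association window after event offset, seconds.
#' @param envelope_window_s,baseline_window_s Passed to [excursion_envelope()].
#' @return Data frame of events: `onset`, `duration`, `type`, `drop` (observed
#'   fractional excursion drop), `evidence`.
#' @export
score_events <- function(airflow, fs_air, spo2 = NULL, fs_spo2 = 1,
                         arousals = NULL, hyp,
                         min_duration_s = 10, apnea_ratio = 0.10,
                         hypopnea_ratio = 0.70, desat_drop = 3,
                         evidence_window_s = 30, envelope_window_s = 4,
                         baseline_window_s = 100) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (is.null(spo2) && is.null(arousals)) {
    warning("no SpO2 and no arousal channel: hypopneas unscorable")
  }
  ee <- excursion_envelope(airflow, fs_air, envelope_window_s,
                           baseline_window_s)
  ratio <- ifelse(ee$baseline > 0, ee$envelope / ee$baseline, 1)
  cand <- which(ratio <= hypopnea_ratio)
  if (length(cand) == 0) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      type = character(), drop = numeric(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
  out <- list()
  for (r in runs) {
    b <- refine_run(ratio, r[1], r[length(r)], fs_air, envelope_window_s)
    run_min <- unname(b["run_min"])
    is_apnea <- run_min <= apnea_ratio
    if (b["duration"] < min_duration_s) next
    onset <- unname(b["onset"]); dur <- unname(b["duration"])
    # discard events starting in a W epoch
    ep <- floor(onset / hyp$epoch_s) + 1L
    if (ep > length(hyp$stages) || hyp$stages[ep] == "W") next
    evidence <- "none"
    if (!is_apnea) {
      ok <- FALSE
      win_lo <- onset; win_hi <- onset + dur + evidence_window_s
      if (!is.null(spo2)) {
        pre_idx <- max(1, round((onset - 60) * fs_spo2)):max(1, round(onset * fs_spo2))
        pre <- stats::median(spo2[pre_idx])
        ev_idx <- round(win_lo * fs_spo2):min(length(spo2), round(win_hi * fs_spo2))
        ev_idx <- ev_idx[ev_idx >= 1]
        if (length(ev_idx) && min(spo2[ev_idx]) <= pre - desat_drop) {
          ok <- TRUE; evidence <- "desaturation"
        }
      }
      if (!ok && !is.null(arousals) &&
          any(arousals >= win_lo & arousals <= win_hi)) {
        ok <- TRUE; evidence <- "arousal"
      }
      if (!ok) next
    }
    out[[length(out) + 1L]] <- data.frame(
      onset = onset, duration = dur,
      type = if (is_apnea) "apnea" else "hypopnea",
      drop = 1 - run_min, evidence = evidence, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      type = character(), drop = numeric(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$onset), , drop = FALSE]
}

#' Respiratory disturbance index from scored events
#'
#' RDI = scored events per hour of sleep (non-W hypnogram time).
#'
#' @param events Data frame of scored events (one row per event).
#' @param hyp A `hypnogram`.
#' @return List with `n_events`, `sleep_hours`, `rdi`.
#' @export
compute_rdi <- function(events, hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  sh <- sleep_hours(hyp)
  if (sh <= 0) stop("zero sleep time: RDI undefined")
  list(n_events = nrow(events), sleep_hours = sh, rdi = nrow(events) / sh)
}
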