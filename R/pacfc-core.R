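#' Analytic signal via the frequency domain
#'
#' Returns the complex analytic signal whose real part is `x`; its argument is
#' the instantaneous phase and its modulus the amplitude envelope.
#'
#' @param x Real numeric vector, length >= 4.
#' @return Complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 4) stop("signal too short for analytic-signal estimation")
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude envelope of a band pair
#'
#' Hilbert-transform step of the coupling analysis: the phase of the
#' low-frequency (phase-modulating) signal and the amplitude envelope of the
#' high-frequency (amplitude-modulated) signal, both from their analytic
#' signals.
#'
#' @param low_band Band-filtered low-frequency signal.
#' @param high_band Band-filtered high-frequency signal, same length.
#' @return List with `phase` (degrees in \[-180, 180)) and `amplitude`
#'   (non-negative envelope).
#' @export
hilbert_phase_amplitude <- function(low_band, high_band) {
  if (length(low_band) != length(high_band)) stop("signals must have equal length")
  if (length(low_band) < 4) stop("signals too short (need >= 4 samples)")
  ph <- Arg(analytic_signal(low_band)) * 180 / pi
  ph[ph >= 180] <- ph[ph >= 180] - 360   # map +180 to -180 for [-180, 180)
  amp <- Mod(analytic_signal(high_band))
  list(phase = ph, amplitude = amp)
}

#' Phase-binned mean-amplitude distribution
#'
#' Partitions the phase axis \[-180, 180) into `n_bins` equal bins (20 bins of
#' 18 degrees by default), averages the amplitude envelope within each bin and
#' normalizes the bin means to sum to one. Empty bins contribute mean
#' amplitude 0 before normalization so that P stays a probability vector.
#'
#' @param phase Phase samples in degrees, \[-180, 180).
#' @param amplitude Amplitude envelope samples, same length.
#' @param n_bins Number of phase bins (>= 2).
#' @return Object of class `phase_amp_dist`: list with `p` (normalized
#'   distribution), `mean_amp` (raw bin means), `edges` (bin edges, degrees),
#'   `n_bins`.
#' @export
bin_mean_amplitude <- function(phase, amplitude, n_bins = 20) {
  if (length(phase) != length(amplitude)) stop("phase/amplitude length mismatch")
  if (n_bins < 2) stop("need at least 2 phase bins")
  if (length(phase) == 0) stop("empty input")
  width <- 360 / n_bins
  j <- pmin(floor((phase + 180) / width), n_bins - 1)  # guard phase == 180
  ji <- as.integer(j) + 1L
  counts <- tabulate(ji, n_bins)
  sums <- numeric(n_bins)
  rs <- rowsum(amplitude, ji)
  sums[as.integer(rownames(rs))] <- rs
  means <- ifelse(counts > 0, sums / pmax(counts, 1L), 0)
  total <- sum(means)
  if (total <= 0) stop("all bin means are zero; cannot normalize")
  structure(list(p = means / total, mean_amp = means,
                 edges = seq(-180, 180, by = width), n_bins = n_bins),
            class = "phase_amp_dist")
}

as_distribution <- function(p) {
  if (inherits(p, "phase_amp_dist")) p <- p$p
  p <- as.numeric(p)
  if (abs(sum(p) - 1) > 1e-8) stop("distribution must sum to 1")
  if (any(p < 0)) stop("distribution must be non-negative")
  p
}

#' Kullback-Leibler distance between discrete distributions
#'
#' `D(P, Q) = sum_j P(j) log(P(j)/Q(j))` in natural log units (nats), with the
#' `0 log 0 = 0` convention. Non-negative, and zero exactly when P equals Q.
#'
#' @param p,q Probability vectors of equal length (or `phase_amp_dist`).
#' @return KL distance in nats.
#' @export
kl_distance <- function(p, q) {
  p <- as_distribution(p); q <- as_distribution(q)
  if (length(p) != length(q)) stop("P and Q must have equal length")
  if (any(p > 0 & q == 0)) stop("infinite divergence: P has mass where Q has none")
  i <- p > 0
  sum(p[i] * log(p[i] / q[i]))
}

#' Shannon entropy of a discrete distribution
#'
#' `H(P) = -sum_j P(j) log P(j)` in nats; bounded by `log(N)`.
#'
#' @param p Probability vector (or `phase_amp_dist`).
#' @return Entropy in nats.
#' @export
shannon_entropy <- function(p) {
  p <- as_distribution(p)
  i <- p > 0
  -sum(p[i] * log(p[i]))
}

#' Modulation index of a phase-amplitude distribution
#'
#' The KL distance of P from the uniform distribution, normalized by its
#' maximum: `MI = [log N - H(P)] / log N`. Zero when the mean amplitude is
#' uniform over phase bins (no coupling), one for a Dirac distribution
#' (maximal coupling).
#'
#' @param p A `phase_amp_dist` or probability vector over N >= 2 bins.
#' @return MI in \[0, 1\].
#' @export
modulation_index <- function(p) {
  p <- as_distribution(p)
  n <- length(p)
  if (n < 2) stop("modulation index undefined for fewer than 2 bins")
  mi <- (log(n) - shannon_entropy(p)) / log(n)
  # clamp tiny negative rounding residue
  min(max(mi, 0), 1)
}

#' Windowed modulation index along a signal pair
#'
#' Slides a window (default 5 s with 50% overlap) along the band-filtered
#' pair and computes the full phase-binning/MI chain inside each window.
#' An incomplete trailing window is discarded.
#'
#' @param low_band,high_band Band-filtered signals, equal length.
#' @param fs Sampling rate, Hz.
#' @param window_s Window length in seconds.
#' @param overlap Fractional overlap in \[0, 1).
#' @param n_bins Phase bins.
#' @return Data frame with `start`, `end` (seconds) and `mi` per window.
#' @export
windowed_mi <- function(low_band, high_band, fs, window_s = 5, overlap = 0.5,
                        n_bins = 20) {
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  wl <- round(window_s * fs)
  if (length(low_band) < wl) stop("signal shorter than one window")
  hop <- max(1L, round(wl * (1 - overlap)))
  starts <- seq(1L, length(low_band) - wl + 1L, by = hop)
  mi <- vapply(starts, function(s) {
    idx <- s:(s + wl - 1L)
    ha <- hilbert_phase_amplitude(low_band[idx], high_band[idx])
    modulation_index(bin_mean_amplitude(ha$phase, ha$amplitude, n_bins))
  }, numeric(1))
  data.frame(start = (starts - 1) / fs, end = (starts - 1 + wl) / fs, mi = mi)
}

#' Default phase/amplitude band pairs of the analysis
#' @return Named list mapping pair label to `c(phase_band, amplitude_band)`.
#' @export
default_pairs <- function() {
  list("theta-gamma" = c("theta", "gamma"),
       "delta-alpha" = c("delta", "alpha"))
}

#' Per-stage modulation-index summary of a night
#'
#' Computes windowed MI per channel for each band pair, assigns each window to
#' the sleep stage of the epoch containing its start, drops windows that span
#' a stage change, and averages MI across windows and channels within each
#' stage. Stages with no surviving windows are absent from the result (never
#' reported as zero).
#'
#' @param decomposition A `band_decomposition` (see [split_bands()]).
#' @param hyp A `hypnogram` aligned to the decomposed recording.
#' @param pairs Named list of band pairs as in [default_pairs()].
#' @param window_s,overlap,n_bins Windowing and binning parameters.
#' @return Data frame with columns `stage`, `pair`, `mi` (mean over windows and
#'   channels), `n_windows` and `n_discarded` (boundary-spanning windows).
#' @export
stage_mi <- function(decomposition, hyp, pairs = default_pairs(),
                     window_s = 5, overlap = 0.5, n_bins = 20) {
  stopifnot(inherits(decomposition, "band_decomposition"),
            inherits(hyp, "hypnogram"))
  fs <- attr(decomposition, "fs")
  epoch_s <- hyp$epoch_s
  out <- list()
  for (pname in names(pairs)) {
    pr <- pairs[[pname]]
    acc <- list()
    discarded <- 0L
    for (ch in names(decomposition)) {
      bands <- decomposition[[ch]]
      if (!all(pr %in% names(bands))) {
        stop("band pair ", pname, " not present in decomposition")
      }
      w <- windowed_mi(bands[[pr[1]]], bands[[pr[2]]], fs = fs,
                       window_s = window_s, overlap = overlap, n_bins = n_bins)
      # stage of the epoch containing the window start; 0-based epochs,
      # half-open [k*epoch, (k+1)*epoch)
      e0 <- floor(w$start / epoch_s)
      e1 <- floor((w$end - 1 / fs) / epoch_s)
      keep_idx <- e0 < length(hyp$stages) & e1 < length(hyp$stages)
      w <- w[keep_idx, , drop = FALSE]; e0 <- e0[keep_idx]; e1 <- e1[keep_idx]
      same <- vapply(seq_along(e0), function(i) {
        length(unique(hyp$stages[(e0[i]:e1[i]) + 1L])) == 1L
      }, logical(1))
      discarded <- discarded + sum(!same)
      w <- w[same, , drop = FALSE]
      w$stage <- hyp$stages[e0[same] + 1L]
      acc[[ch]] <- w
    }
    all_w <- do.call(rbind, acc)
    if (nrow(all_w) == 0) next
    agg <- stats::aggregate(mi ~ stage, data = all_w, FUN = mean)
    cnt <- stats::aggregate(mi ~ stage, data = all_w, FUN = length)
    out[[pname]] <- data.frame(stage = agg$stage, pair = pname, mi = agg$mi,
                               n_windows = cnt$mi, n_discarded = discarded,
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
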