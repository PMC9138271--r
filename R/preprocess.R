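#' Default EEG frequency bands
#'
#' The six analysis bands: very low frequency 0.1-1 Hz, delta 1-3, theta 4-7,
#' alpha 8-13, beta 14-30, gamma 31-100 Hz. At a 200 Hz sampling rate the
#' gamma upper edge is capped at 0.99 x Nyquist (99 Hz) when filters are
#' designed.
#'
#' @return Data frame with columns `name`, `f_low`, `f_high`.
#' @export
default_bands <- function() {
  data.frame(
    name   = c("vlf", "delta", "theta", "alpha", "beta", "gamma"),
    f_low  = c(0.1, 1, 4, 8, 14, 31),
    f_high = c(1, 3, 7, 13, 30, 100),
    stringsAsFactors = FALSE)
}

#' Anti-alias and detrend EEG channels
#'
#' Zero-phase (forward-backward) 4th-order Butterworth low-pass at
#' `min(100, 0.99 x Nyquist)` Hz followed by a 0.5 Hz high-pass, applied to the
#' named EEG channels. Zero-phase application squares the magnitude response
#' (effective 8th order) and introduces no phase distortion, which the
#' downstream phase estimation requires.
#'
#' @param rec A `psg_recording`.
#' @param eeg_channels Channels to filter (default the central EEG pair).
#' @param lowpass_hz,highpass_hz Cutoffs in Hz.
#' @return The recording with filtered EEG channels.
#' @export
antialias_and_detrend <- function(rec, eeg_channels = c("C3-M1", "C4-M2"),
                                  lowpass_hz = 100, highpass_hz = 0.5) {
  stopifnot(inherits(rec, "psg_recording"))
  eeg_channels <- intersect(eeg_channels, names(rec$channels))
  if (length(eeg_channels) == 0) stop("no EEG channels present")
  for (ch in eeg_channels) {
    fs <- rec$fs[[ch]]
    if (fs < 2) stop("sampling rate too low for 0.5 Hz high-pass")
    lp <- min(lowpass_hz, 0.99 * fs / 2)
    x <- butter_zerophase(rec$channels[[ch]], fs, "low", lp)
    x <- butter_zerophase(x, fs, "high", highpass_hz)
    rec$channels[[ch]] <- x
  }
  rec
}

#' Band-pass decomposition of EEG channels
#'
#' Splits each EEG channel into the requested frequency bands with zero-phase
#' 4th-order Butterworth band-pass filters. A band's upper edge is capped at
#' 0.99 x Nyquist (so gamma 31-100 Hz is realized as 31-99 Hz at 200 Hz); a
#' band whose lower edge reaches the cap is rejected.
#'
#' @param rec A `psg_recording` (preprocessed).
#' @param bands Data frame like [default_bands()].
#' @param eeg_channels Channels to decompose.
#' @return A `band_decomposition`: per-channel named list of filtered signals,
#'   with attributes `fs` and `bands`.
#' @export
split_bands <- function(rec, bands = default_bands(),
                        eeg_channels = c("C3-M1", "C4-M2")) {
  stopifnot(inherits(rec, "psg_recording"))
  eeg_channels <- intersect(eeg_channels, names(rec$channels))
  if (length(eeg_channels) == 0) stop("no EEG channels present")
  if (any(bands$f_low < 0) || any(bands$f_low >= bands$f_high)) {
    stop("invalid band edges")
  }
  fs <- unique(rec$fs[eeg_channels])
  if (length(fs) != 1) stop("EEG channels must share one sampling rate")
  nyq <- fs / 2
  hi <- pmin(bands$f_high, 0.99 * nyq)
  if (any(bands$f_low >= hi)) {
    stop("band exceeds Nyquist after capping: ",
         paste(bands$name[bands$f_low >= hi], collapse = ", "))
  }
  out <- lapply(eeg_channels, function(ch) {
    x <- rec$channels[[ch]]
    sig <- lapply(seq_len(nrow(bands)), function(i) {
      butter_zerophase(x, fs, "pass", c(bands$f_low[i], hi[i]))
    })
    stats::setNames(sig, bands$name)
  })
  names(out) <- eeg_channels
  structure(out, fs = fs, bands = transform(bands, f_high = hi),
            class = "band_decomposition")
}

# ---- FastICA ---------------------------------------------------------------

#' FastICA with symmetric decorrelation
#'
#' Fixed-point independent component analysis using the logcosh contrast.
#' Rows of the input are channels; the data are centred and whitened first.
#'
#' @param x Numeric matrix, channels x samples.
#' @param n_components Number of components (default all channels).
#' @param max_iter Fixed-point iteration cap.
#' @param tol Convergence tolerance on the rotation update.
#' @param seed Integer seed for the random initial rotation.
#' @param max_restarts Fresh random restarts on non-convergence before erroring.
#' @return List with `S` (components x samples), `A` (mixing, channels x comp),
#'   `W` (unmixing, comp x channels), `center`, `converged`.
#' @export
fast_ica <- function(x, n_components = nrow(x), max_iter = 200, tol = 1e-6,
                     seed = 1, max_restarts = 5) {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  nc <- n_components
  center <- rowMeans(x)
  xc <- x - center
  cv <- tcrossprod(xc) / ncol(xc)
  eg <- eigen(cv, symmetric = TRUE)
  keep <- seq_len(nc)
  K <- diag(1 / sqrt(eg$values[keep]), nc) %*% t(eg$vectors[, keep, drop = FALSE])
  z <- K %*% xc   # whitened

  sym_decorr <- function(w) {
    sw <- w %*% t(w)
    e <- eigen(sw, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), nc) %*% t(e$vectors) %*% w
  }
  for (r in seq_len(max_restarts)) {
    set.seed(seed + r - 1L)
    w <- sym_decorr(matrix(stats::rnorm(nc * nc), nc))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wz <- w %*% z
      g <- tanh(wz)
      gp <- 1 - g^2
      w_new <- (g %*% t(z)) / ncol(z) - diag(rowMeans(gp), nc) %*% w
      w_new <- sym_decorr(w_new)
      delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
      w <- w_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) break
  }
  if (!converged) stop("FastICA failed to converge after ", max_restarts,
                       " restarts")
  W <- w %*% K                       # unmixing: comp x channels
  A <- MASS_ginv(W)                  # mixing: channels x comp
  list(S = W %*% xc, A = A, W = W, center = center, converged = converged)
}

# Moore-Penrose pseudoinverse via SVD (avoids a MASS dependency for one call)
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > max(tol * s$d[1], 0)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

component_power_fraction <- function(s, fs, f_lo, f_hi) {
  n <- length(s)
  sp <- Mod(stats::fft(s))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  tot <- sum(sp[half])
  if (tot == 0) return(0)
  sum(sp[half & freqs >= f_lo & freqs <= f_hi]) / tot
}

#' Remove stereotyped artifact components with FastICA
#'
#' Decomposes the EEG channels into independent components and zeroes
#' components matching automated rejection rules: (a) line noise - more than
#' `line_frac` of spectral power within 1 Hz of `line_hz`; (b) blink/transient -
#' sample kurtosis above `kurtosis_max`; (c) muscle - power above 20 Hz
#' exceeding `muscle_ratio` times the power below 20 Hz together with low
#' lag-one autocorrelation. With only two EEG channels the decomposition has
#' two components, so removal is best-effort; the rules and thresholds are
#' configurable.
#'
#' @param rec A `psg_recording`.
#' @param eeg_channels Channels to decompose (need >= 2).
#' @param line_hz Mains frequency, Hz.
#' @param line_frac,kurtosis_max,muscle_ratio,muscle_acf Rule thresholds.
#' @param seed Seed for the ICA initial rotation.
#' @return List with `recording` (cleaned) and `report` (data frame of
#'   components, rule flags and whether each was removed).
#' @export
remove_artifact_components <- function(rec, eeg_channels = c("C3-M1", "C4-M2"),
                                       line_hz = 50, line_frac = 0.5,
                                       kurtosis_max = 10, muscle_ratio = 4,
                                       muscle_acf = 0.5, seed = 1) {
  stopifnot(inherits(rec, "psg_recording"))
  eeg_channels <- intersect(eeg_channels, names(rec$channels))
  if (length(eeg_channels) < 2) stop("ICA needs at least 2 channels")
  fs <- unique(rec$fs[eeg_channels])
  if (length(fs) != 1) stop("EEG channels must share one sampling rate")
  x <- do.call(rbind, rec$channels[eeg_channels])
  ica <- fast_ica(x, seed = seed)
  nc <- nrow(ica$S)
  rules <- character(nc)
  for (i in seq_len(nc)) {
    s <- ica$S[i, ]
    hit <- character(0)
    if (component_power_fraction(s, fs, line_hz - 1, line_hz + 1) > line_frac) {
      hit <- c(hit, "line")
    }
    k <- mean((s - mean(s))^4) / stats::var(s)^2
    if (k > kurtosis_max) hit <- c(hit, "blink")
    hi <- component_power_fraction(s, fs, 20, fs / 2)
    lo <- component_power_fraction(s, fs, 0, 20)
    a1 <- stats::cor(s[-1], s[-length(s)])
    if (lo > 0 && hi / lo > muscle_ratio && a1 < muscle_acf) {
      hit <- c(hit, "muscle")
    }
    rules[i] <- paste(hit, collapse = "+")
  }
  removed <- nzchar(rules)
  S_clean <- ica$S
  S_clean[removed, ] <- 0
  x_clean <- ica$A %*% S_clean + ica$center
  for (j in seq_along(eeg_channels)) {
    rec$channels[[eeg_channels[j]]] <- as.numeric(x_clean[j, ])
  }
  list(recording = rec,
       report = data.frame(component = seq_len(nc), rule = rules,
                           removed = removed, stringsAsFactors = FALSE))
}
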