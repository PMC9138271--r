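# Butterworth filters as cascaded second-order sections.
#
# Direct transfer-function (b, a) realizations of 4th-order Butterworth
# filters are numerically unstable at the normalized cutoffs this pipeline
# needs (a 0.1-1 Hz band at a 200 Hz rate puts poles at |z| ~ 1 - 1e-3 with
# an 8th-order polynomial), so filters are designed in zero-pole-gain form
# and applied section by section.

butter_sections <- function(order, type, f, fs) {
  stopifnot(order %% 2 == 0)
  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  warp <- function(fc) 2 * tan(pi * fc / fs)   # bilinear prewarp, T = 1

  if (type == "low") {
    wc <- warp(f)
    s_poles <- wc * proto
    zero_kind <- rep("nyquist", 2)     # all zeros at z = -1
    wref <- 0
  } else if (type == "high") {
    wc <- warp(f)
    s_poles <- wc / proto
    zero_kind <- rep("dc", 2)          # all zeros at z = +1
    wref <- pi
  } else if (type == "pass") {
    w1 <- warp(f[1]); w2 <- warp(f[2])
    w0 <- sqrt(w1 * w2); B <- w2 - w1
    s_poles <- unlist(lapply(proto, function(p) {
      # s_lp = (s^2 + w0^2) / (B s) = p  ->  s^2 - B p s + w0^2 = 0
      disc <- sqrt(as.complex((B * p)^2 / 4 - w0^2))
      c(B * p / 2 + disc, B * p / 2 - disc)
    }))
    zero_kind <- c("dc", "nyquist")    # one z = +1 and one z = -1 per section
    wref <- 2 * atan(w0 / 2)
  } else {
    stop("unknown filter type: ", type)
  }

  z_poles <- (2 + s_poles) / (2 - s_poles)   # bilinear transform
  # group into conjugate-pair biquads
  upper <- z_poles[Im(z_poles) > 1e-12]
  realp <- Re(z_poles[abs(Im(z_poles)) <= 1e-12])
  pairs <- lapply(upper, function(p) c(p, Conj(p)))
  if (length(realp) >= 2) {
    for (i in seq(1, length(realp) - 1, by = 2)) {
      pairs[[length(pairs) + 1]] <- as.complex(realp[c(i, i + 1)])
    }
  }
  stopifnot(length(pairs) == length(z_poles) / 2)

  zero_poly <- c(dc = -1, nyquist = 1)   # (z - 1) or (z + 1) factors
  sections <- lapply(pairs, function(pp) {
    a <- c(1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2]))
    b <- Re(stats::convolve(c(1, zero_poly[[zero_kind[1]]]),
                            rev(c(1, zero_poly[[zero_kind[2]]])),
                            type = "open"))
    # normalize section gain at the reference frequency
    zr <- exp(-1i * wref)
    g <- Mod(sum(b * zr^(0:2)) / sum(a * zr^(0:2)))
    list(b = b / g, a = a)
  })
  sections
}

#' Zero-phase Butterworth filtering
#'
#' Designs an `order`-th order Butterworth filter (bilinear transform of the
#' analog prototype) and applies it forward and backward (`signal::filtfilt`)
#' as a cascade of second-order sections, so the result is zero-phase with
#' the squared magnitude response.
#'
#' @param x Signal.
#' @param fs Sampling rate, Hz.
#' @param type `"low"`, `"high"` or `"pass"`.
#' @param f Cutoff frequency in Hz (scalar, or `c(lo, hi)` for `"pass"`).
#' @param order Filter order (even; band-pass uses `order` pole pairs).
#' @return Filtered signal, same length.
#' @details The signal is extended at both ends by odd reflection (continuous
#'   in value and slope) before the forward and backward passes, so filter
#'   start-up transients decay inside the padding rather than in the data.
#' @keywords internal
butter_zerophase <- function(x, fs, type, f, order = 4) {
  n <- length(x)
  secs <- butter_sections(order, type, f, fs)
  L <- min(n - 1, max(100L, round(6 * fs)))
  xp <- c(2 * x[1] - x[(L + 1):2], x, 2 * x[n] - x[(n - 1):(n - L)])
  run <- function(z) {
    for (sec in secs) {
      z <- as.numeric(signal::filter(signal::Arma(b = sec$b, a = sec$a), z))
    }
    z
  }
  xp <- run(xp)
  xp <- rev(run(rev(xp)))
  xp[(L + 1):(L + n)]
}
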