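#' SDNN heart-rate-variability measure
#'
#' Sample standard deviation (n - 1 denominator) of normal-to-normal
#' inter-beat intervals. Intervals outside the physiologic 200-3000 ms range
#' are flagged with a warning but retained (the caller decides on exclusion).
#'
#' @param rr Normal-to-normal intervals, milliseconds (> 0, length >= 2).
#' @return SDNN in milliseconds.
#' @export
hrv_sdnn <- function(rr) {
  if (length(rr) < 2) stop("need at least 2 intervals")
  if (any(rr <= 0)) stop("intervals must be positive")
  out_of_range <- rr < 200 | rr > 3000
  if (any(out_of_range)) {
    warning(sum(out_of_range), " interval(s) outside 200-3000 ms")
  }
  stats::sd(rr)
}

#' Pearson correlation between per-subject measures
#'
#' Pearson r with a two-sided p-value from the t distribution on n - 2
#' degrees of freedom; used for the scientific controls (MI vs arousal index,
#' PLM index, HRV, and MI vs clinical scores).
#'
#' @param x,y Paired numeric vectors, equal length >= 3.
#' @param pair Optional label for the variable pair.
#' @param stage Optional sleep-stage label.
#' @return Data frame row: `pair`, `stage`, `r`, `p`, `n`.
#' @export
correlate <- function(x, y, pair = NA_character_, stage = NA_character_) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(pair = pair, stage = stage, r = unname(ct$estimate),
             p = ct$p.value, n = length(x), stringsAsFactors = FALSE)
}

#' Welch two-sample comparison of group values
#'
#' Welch's t-test (unequal variances) on per-subject values, e.g. stage MI
#' between the RDI groups or the demographic columns.
#'
#' @param low,high Numeric vectors for the two groups (each n >= 2).
#' @return List with `t`, `df`, `p`, and per-group `mean`/`sd`/`n`.
#' @export
compare_groups <- function(low, high) {
  if (length(low) < 2 || length(high) < 2) stop("each group needs n >= 2")
  tt <- stats::t.test(low, high, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
       mean = c(low = mean(low), high = mean(high)),
       sd = c(low = stats::sd(low), high = stats::sd(high)),
       n = c(low = length(low), high = length(high)))
}

#' Welch t-test from summary statistics
#'
#' Same comparison as [compare_groups()] when only group means, SDs and sizes
#' are available (e.g. published demographics tables).
#'
#' @param mean1,sd1,n1 First group's summary.
#' @param mean2,sd2,n2 Second group's summary.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  se2 <- sd1^2 / n1 + sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(se2)
  df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Bayesian posterior for a standardized two-group difference
#'
#' Posterior sampling for the standardized difference in group means
#' (effect size `delta = (mu1 - mu2) / sqrt((sigma1^2 + sigma2^2) / 2)`)
#' under independent normal likelihoods per group with Jeffreys priors
#' (`p(mu, sigma^2) proportional to 1/sigma^2`). The posterior is conjugate -
#' `sigma_k^2` is scaled-inverse-chi-squared and `mu_k | sigma_k^2` normal -
#' so draws are exact, with no sampler convergence concerns. The sample is
#' judged sufficient for the group contrast when the 95% HDI of the effect
#' size excludes zero.
#'
#' @param low,high Per-subject values for the two groups (each n >= 2).
#' @param draws Number of posterior draws.
#' @param seed Integer seed.
#' @param hdi_mass HDI probability mass.
#' @return List with `effect_draws`, `hdi` (`c(lower, upper)`),
#'   `sufficient_sample` (HDI excludes 0), `mean`/`sd` per group, and
#'   `posterior_mean_effect`.
#' @export
bayesian_group_posterior <- function(low, high, draws = 4000, seed = 1,
                                     hdi_mass = 0.95) {
  if (length(low) < 2 || length(high) < 2) stop("each group needs n >= 2")
  set.seed(seed)
  draw_group <- function(x) {
    n <- length(x); xb <- mean(x); s2 <- stats::var(x)
    sigma2 <- (n - 1) * s2 / stats::rchisq(draws, df = n - 1)
    mu <- stats::rnorm(draws, xb, sqrt(sigma2 / n))
    list(mu = mu, sigma2 = sigma2)
  }
  g1 <- draw_group(low); g2 <- draw_group(high)
  eff <- (g1$mu - g2$mu) / sqrt((g1$sigma2 + g2$sigma2) / 2)
  h <- hdi(eff, hdi_mass)
  list(effect_draws = eff, hdi = h,
       sufficient_sample = (h["lower"] > 0 || h["upper"] < 0),
       mean = c(low = mean(low), high = mean(high)),
       sd = c(low = stats::sd(low), high = stats::sd(high)),
       posterior_mean_effect = mean(eff))
}

#' Control-correlation grid
#'
#' Correlates per-subject stage MI with each control variable (arousal index,
#' PLM index, SDNN) and with the clinical scores, per pair and stage —
#' the tabular equivalent of the controls figure.
#'
#' @param subject_features Output of [subject_feature_table()].
#' @param control_cols Metadata columns to correlate against.
#' @param adjust P-value adjustment method (`"none"` by default; `"holm"`
#'   available).
#' @return Data frame of [correlate()] rows plus `control` and `p_adj`.
#' @export
control_correlations <- function(subject_features,
                                 control_cols = c("arousal_index", "plm_index",
                                                  "sdnn"),
                                 adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  mi_cols <- grep("^mi\\.", names(subject_features), value = TRUE)
  rows <- list()
  for (mc in mi_cols) {
    parts <- strsplit(mc, ".", fixed = TRUE)[[1]]
    for (cc in control_cols) {
      ok <- stats::complete.cases(subject_features[[mc]],
                                  subject_features[[cc]])
      r <- correlate(subject_features[[mc]][ok], subject_features[[cc]][ok],
                     pair = parts[2], stage = parts[3])
      r$control <- cc
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = if (adjust == "none") "none"
                               else "holm")
  out
}
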