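---
title: "Phase-amplitude coupling in sleep EEG: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-amplitude coupling in sleep EEG: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pacsleep)
```

## The measurement

Phase-amplitude cross-frequency coupling (PACFC) quantifies how strongly the
amplitude of a fast cortical rhythm is modulated by the phase of a slow one.
`pacsleep` measures it with the Kullback-Leibler modulation index. For a
band-filtered pair of signals the chain is:

1. **Analytic signal.** The Hilbert transform (FFT construction) gives the
   instantaneous phase $\phi(t)$ of the low-frequency signal and the amplitude
   envelope $A(t)$ of the high-frequency signal
   (`hilbert_phase_amplitude()`). Phase is expressed in degrees on
   $[-180, 180)$.
2. **Phase binning.** The phase axis is divided into $N = 20$ bins of
   $18^\circ$; the mean envelope per bin, normalized to unit sum, is the
   distribution $P(j)$ (`bin_mean_amplitude()`).
3. **Modulation index.** With $U$ the uniform distribution,
   $D_{KL}(P, U) = \log N - H(P)$ where $H$ is Shannon entropy, and
   $$\mathrm{MI} = \frac{\log N - H(P)}{\log N} \in [0, 1],$$
   zero for uniform $P$ (no coupling) and one for a Dirac $P$
   (`modulation_index()`).

All logarithms are natural. The normalization makes the base irrelevant —
$\mathrm{MI}$ is a ratio of entropies — which the tests assert explicitly.

MI is computed in 5 s windows with 50% overlap (`windowed_mi()`), and each
window is assigned to the sleep stage of the 30 s epoch containing its start.
Windows that span a stage transition are discarded rather than mixed. Per
subject, stage and band pair, window MIs are averaged across windows and
across the two central EEG derivations (C3-M1, C4-M2); a stage with no
surviving windows is reported absent, never as zero. Averaging (rather than
pooling or medians) and channel averaging are deliberate defaults: they are
the simplest summary consistent with one value per subject and stage, and
both are exposed as code paths that a user can change.

The analysed band pairs are theta (4-7 Hz) phase with gamma (31-99 Hz)
amplitude, and delta (1-3 Hz) phase with alpha (8-13 Hz) amplitude, from the
six-band decomposition (VLF 0.1-1, delta 1-3, theta 4-7, alpha 8-13, beta
14-30, gamma 31-100 Hz). At a 200 Hz sampling rate the printed gamma edge
touches the Nyquist frequency, so filters cap any band edge at
$0.99 \times$ Nyquist (gamma is realized as 31-99 Hz).

## Filtering

All filters are 4th-order Butterworth, applied forward and backward so the
net result is zero-phase with the squared magnitude response. Zero-phase
application is not optional here: a causal filter would shift the
low-frequency phase relative to the high-frequency envelope and bias the MI.

Two implementation details matter numerically:

- **Second-order sections.** A transfer-function realization of these filters
  is unstable at the normalized cutoffs the pipeline needs (the 0.1-1 Hz band
  at 200 Hz puts eight poles at $|z| \approx 0.999$ in one polynomial).
  Filters are therefore designed in zero-pole-gain form — analog Butterworth
  prototype, band transform, bilinear transform with prewarping — and applied
  as cascaded biquads (`R/filters.R`). During development the section designs
  were checked against an independent SOS implementation to five decimals
  across all six bands.
- **Edge handling.** Signals are extended by odd reflection (continuous in
  value and slope) before the forward and backward passes, so start-up
  transients decay inside the padding. The padding is
  $\min(n - 1, 6 f_s)$ samples, several time constants of the slowest
  section.

A consequence worth knowing: a 4th-order low-pass at 100 Hz attenuates a
120 Hz tone by only $\sim 23$ dB (power, after the double pass). That is the
mathematics of the specified filter, not an implementation defect, and the
tests assert the realizable figure.

## Artifact handling

`remove_artifact_components()` decomposes the EEG channels with FastICA
(symmetric decorrelation, logcosh contrast, implemented in-package) and
zeroes components matching three automated rules, each with a configurable
threshold:

- *line*: $> 50\%$ of spectral power within $\pm 1$ Hz of 50 Hz;
- *blink/transient*: sample kurtosis $> 10$;
- *muscle*: power above 20 Hz exceeding four times the power below, with
  lag-one autocorrelation $< 0.5$.

With only two EEG channels the decomposition has two components, so removal
is best-effort by construction: a flagged component mixes artifact with
brain signal, and rejecting it costs signal. The synthetic generator logs
every injected artifact, and the tests validate removal against that log
(50 Hz power reduced by $\ge 10$ dB; clean input reconstructed with
$r > 0.99$ and zero flags) rather than against an unobservable ideal.

## The synthetic cohort

No patient recordings ship with the package, so the generator module is the
study population. Its defaults are the study conditions, chosen once:

- **Groups.** 42 subjects with RDI $\le 15$/h (RDI $\sim 9.30 \pm 3.26$,
  truncated at the cutoff) and 44 with RDI $> 15$/h ($27.96 \pm 12.47$).
  A boundary RDI of exactly 15 belongs to the low group, matching the group
  labels.
- **Coupling signal.** Within each stage-labelled segment the EEG model is
  multiplicative amplitude modulation,
  $x(t) = \sum_{\text{pairs}} a_h [1 + m_s \cos \phi_l(t)] \sin(2\pi f_h t)
  + a_l \sin(2\pi f_l t) + \text{pink noise}$, with carriers at 5.5/60 Hz
  (theta-gamma) and 2/10 Hz (delta-alpha). This is the standard PAC test
  signal; its 20-bin distribution is $P(j) \propto 1 + \cos \phi_j$ at
  $m = 1$, so the MI it should produce is analytic and the generator-analyser
  loop is checkable end to end. Carrier amplitudes give a band-filtered SNR
  of about 3 in the amplitude bands (6 in the phase bands) over 1/f noise of
  10 uV SD - enough that finite-sample MI bias is small but nonzero.
- **Stage-group structure.** Group-level coupling depths encode the
  qualitative pattern under study: theta-gamma lower in the high-RDI group at
  every stage (largest gap at N1, smallest at N2); delta-alpha lower at REM
  and N1, *higher* at N2, and equal at N3 and W. Subject depths scatter
  around the group means (SD 0.04).
- **Clinical link.** ESS $= 15.5 - 8 \bar m_{\theta\gamma}^{N2,N3} +
  \mathcal N(0, 4.2)$, clamped to $[0, 24]$: both groups land near
  $11 \pm 4.5$ points with a slightly higher high-RDI mean, while remaining
  individually linked to N2/N3 theta-gamma coupling. Arousal index, PLM index
  and SDNN are drawn independently of coupling, because the study's controls
  found no association and the generator must reproduce that null.
- **Hypnograms.** A first-order Markov chain over 30 s epochs, starting in W,
  with a transition matrix tuned to a stationary occupancy of about 5% W,
  10% N1, 51% N2, 14% N3, 20% REM. For the cohort's short recordings
  (default 10 minutes per subject) a balanced block hypnogram — equal time in
  all five stages — replaces the Markov draw so that every stage is
  observable per subject; full-night Markov hypnograms are used wherever
  duration, not stage coverage, is the point (respiratory scoring,
  occupancy tests).
- **Respiratory channels.** Airflow is an amplitude-modulated sinusoid at
  0.25 Hz; planted events drop the excursion by $\ge 92\%$ (apneas) or
  40-85% (hypopneas) for 10-40 s (durations uniform; the scoring rule states
  only the 10 s floor), with Poisson-distributed counts targeting the
  subject's RDI. Every hypopnea carries qualifying evidence: a 3.5-6%
  desaturation lagging the event, or an arousal marker. Events are planted
  only inside sleep with a minimum separation of 20 s.

What the generator does *not* emulate: spindles, K-complexes and other
transients; non-stationary coupling within a stage; cross-channel coupling
asymmetries; realistic breath-shape variability; obstructive versus central
event morphology. Passing tests therefore demonstrate that the pipeline
recovers the structure this model plants — direction, ordering, calibration
— not that it would reach any particular accuracy on clinical recordings.

## Respiratory event scoring

The rule engine operationalizes the quantitative scoring criteria: apnea
when the breath-excursion envelope falls to $\le 10\%$ of the pre-event
baseline for $\ge 10$ s; hypopnea at $\le 70\%$ for $\ge 10$ s with either a
$\ge 3\%$ desaturation from the pre-event SpO2 level or an arousal within
30 s after the event. Intervals meeting the apnea criterion are scored as
apneas only. Events whose onset lies in a wake epoch are discarded, and RDI
divides the event count by non-wake hours.

Two free choices had to be made where the criteria are silent:

- *Baseline.* "Pre-event baseline" is a rolling median of the excursion
  envelope over the preceding 100 s, median rather than mean so that the
  baseline ignores the events themselves and short dropouts.
- *Boundaries.* The envelope is a peak-to-trough measure over a sliding
  window of one breath period (4 s), which smears event edges by half a
  window on each side. Durations are measured at a level one quarter of the
  way from the event's own envelope floor back to baseline — below the
  half-way level that a window straddling the boundary produces for
  quasi-sinusoidal breathing — and compensated by exactly one window. On
  planted rectangular events this recovers durations to within about one
  second, which the boundary tests (12 s at 95% scored; 8 s at 95% not
  scored) pin down.

At very high event densities (RDI $\gtrsim 40$/h) adjacent events can merge
and the rolling baseline starts to erode, so counts recover the plant
exactly on clean moderate-density nights and remain within a few percent at
the extremes; the third analysis script reports this behaviour on the full
cohort (RDI recovery $r \approx 0.98$).

## Machine-learning evaluation

The evaluation protocol mirrors the study design: a polynomial-kernel SVM,
kernel coefficient fixed at 0.25, with degree and cost selected by grid
search over the integers 1-10. The source text describes "10-fold
cross-validation by taking 75% of the data for training and 25% for
testing", which is not canonical 10-fold; it is implemented as **10 repeated
stratified random 75/25 splits**, matching the stated fractions. All model
selection happens inside the training portion (an inner 75/25 holdout); the
SVM's feature scaling is fitted on training rows only. A dedicated leak test
plants a feature that encodes the label in test rows only and asserts that
accuracy does not move.

Stage classification uses window-level feature vectors (theta-gamma and
delta-alpha MI on both channels); clinical prediction uses subject-level
per-stage MI with support-vector regression. The study never defines SVR
"prediction accuracy". The package's default is a **median-error skill
score**,
$$100 \left(1 - \frac{\mathrm{med}\,|\hat y - y|}{\mathrm{med}\,|\mathrm{med}(y_{tr}) - y|}\right),$$
i.e. improvement over predicting the training median: an uninformative model
scores near zero and a perfect one 100. A range-normalized median error,
$R^2$ and a within-tolerance fraction are selectable alternatives. The skill
form was chosen because accuracy definitions that normalize by the target's
range place an uninformative predictor at 75-85% — above the 75% decision
threshold — which would make the threshold meaningless; the null-calibration
tests (permuted targets fall below threshold in $\ge 9/10$ splits) depend on
this property and document it.

The 75% decision threshold itself is configuration, reported alongside the
highest-density interval of the pooled MI distribution
(`accuracy_threshold()`); the HDI is computed by the standard sorted-window
search and cross-checked against an independent implementation in the tests.

## Control statistics

- **SDNN**: sample standard deviation ($n - 1$) of normal-to-normal RR
  intervals, with intervals outside 200-3000 ms flagged.
- **Correlations**: Pearson $r$ with two-sided $t$-distribution p-values,
  over the grid of band pair x stage x control variable (arousal index, PLM
  index, SDNN). No multiple-testing correction by default, matching the
  original analysis; Holm adjustment is available.
- **Group contrasts**: Welch's $t$-test (the safe reading of an unqualified
  "t-test"), both from raw values and from published-style summary
  statistics, with a consistency test tying the two together.
- **Bayesian posterior**: the standardized group difference
  $\delta = (\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}$ under
  independent normal likelihoods with Jeffreys priors. The posterior is
  conjugate (scaled-inverse-$\chi^2$ variances, conditionally normal means),
  so effect-size draws are exact — no MCMC, no convergence diagnostics, and
  bit-reproducible under a seed. This is a deliberate simplification of
  heavy-tailed two-group estimation models: with the generator's normal
  group distributions the t-likelihood adds robustness the data never need,
  while exact draws make the 200-replicate coverage calibration cheap. The
  sample-size check reports whether the 95% HDI of $\delta$ excludes zero.

## Problem sizes and numerical choices

The shipped analyses and tests run at sizes chosen to exercise every code
path at desk scale: the default cohort is 86 subjects with 10 minutes of
two-channel 200 Hz EEG each (the stage-wise group pattern reproduces with
$p < 10^{-11}$ at every constrained cell); parameter-recovery sweeps use
one-minute single-stage nights, 10 replicates per coupling depth;
classification uses a few hundred stratified windows. Empty phase bins
receive mean amplitude zero before normalization (they essentially never
occur with 5 s windows and $\ge 1$ Hz phase bands). MI values are clamped
against tiny negative rounding residue. Degenerate inputs — constant
distributions, zero-variance targets, absent channels, wake-only hypnograms
— raise errors rather than propagate.

## Known limitations

- With two EEG channels, ICA cleanup is structurally limited; heavy
  contamination costs signal.
- The respiratory scorer's boundary resolution is about one breath period;
  sub-second event timing is out of reach by construction.
- Short balanced recordings make stage MI estimates noisier than full
  nights; between-subject scatter in the synthetic cohort is dominated by
  estimation noise at the default depth SD.
- Synthetic-cohort classification and prediction accuracies are properties
  of the generator configuration, not forecasts of performance on clinical
  data.
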