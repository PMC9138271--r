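# pacsleep

Phase-amplitude cross-frequency coupling (PACFC) analysis of sleep EEG for
obstructive sleep apnea (OSA) research.

In OSA, recurrent upper-airway collapse fragments sleep and is suspected to
disturb sensorimotor cortical coordination. One way to quantify that
coordination is cross-frequency coupling: the degree to which the amplitude
of a fast EEG rhythm (gamma, alpha) is modulated by the phase of a slow one
(theta, delta) at the central electrodes C3/C4. `pacsleep` implements the
full analysis chain for this question — band decomposition, the
Kullback-Leibler modulation index per sleep stage, rule-based apnea/hypopnea
scoring, SVM/SVR evaluation of stage classification and clinical-score
prediction, and the scientific-control statistics — together with a
synthetic polysomnography generator that stands in for a patient cohort, so
the entire pipeline is testable and reproducible without any protected
health data.

## The statistic

For a phase series $\phi(t)$ (Hilbert phase of the low band) and amplitude
envelope $A(t)$ (Hilbert magnitude of the high band), the phase axis
$[-180^\circ, 180^\circ)$ is split into $N = 20$ bins of $18^\circ$ and the
normalized mean amplitude per bin forms a distribution $P(j)$. With

$$D_{KL}(P, U) = \log N - H(P), \qquad H(P) = -\sum_j P(j) \log P(j),$$

the modulation index is

$$\mathrm{MI} = \frac{D_{KL}(P, U)}{\log N} \in [0, 1],$$

zero when amplitude is uniform over phase (no coupling), one for a Dirac
distribution. MI is computed in 5 s windows with 50% overlap and averaged
per subject x sleep stage x band pair (theta-gamma, delta-alpha).

## Worked example

```r
library(pacsleep)

# a night with known coupling: theta-gamma depth 0.6 in N2, 0.2 in REM
hyp  <- hypnogram(rep(c("N2", "REM"), each = 2))
prof <- coupling_profile("theta-gamma",
                         c(W = 0, N1 = 0, N2 = 0.6, N3 = 0, REM = 0.2))
rec  <- generate_coupled_eeg(hyp, list(prof), seed = 1)
dec  <- split_bands(antialias_and_detrend(rec))
stage_mi(dec, hyp, pairs = default_pairs()["theta-gamma"])
#>   stage        pair          mi n_windows n_discarded
#> 1    N2 theta-gamma 0.026064419        46           2
#> 2   REM theta-gamma 0.003064185        46           2
```

The N2 windows, generated with three times the coupling depth of REM, come
back with about eight times the modulation index (the MI-depth curve is
monotone but not linear); one window per channel spanning each stage change
was discarded.

The numbered scripts under `analysis/` run the full study on the synthetic
cohort and write tables to `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # 42 + 44 subjects, metadata table
Rscript analysis/02_stage_mi.R          # preprocessing + stage MI + group contrast
Rscript analysis/03_score_respiration.R # apnea/hypopnea scoring vs ground truth
Rscript analysis/04_ml_eval.R           # SVM stages, SVR RDI/ESS, HDI threshold
Rscript analysis/05_controls.R          # control correlations, Bayesian posterior
```

From a run of `02` (Welch t-test per stage, low vs high RDI group):

```
theta-gamma W    low 0.0093  high 0.0037  p = 1.49e-24
theta-gamma N1   low 0.0150  high 0.0048  p = 5.83e-24
theta-gamma N2   low 0.0226  high 0.0165  p = 1.56e-12
theta-gamma N3   low 0.0263  high 0.0131  p = 1.65e-34
theta-gamma REM  low 0.0118  high 0.0048  p = 5.21e-23
delta-alpha W    low 0.0041  high 0.0041  p = 0.891
delta-alpha N1   low 0.0053  high 0.0024  p = 4.2e-20
delta-alpha N2   low 0.0041  high 0.0073  p = 3.12e-23
delta-alpha N3   low 0.0066  high 0.0070  p = 0.0848
delta-alpha REM  low 0.0064  high 0.0030  p = 8.95e-24
```

— theta-gamma coupling is lower in the high-RDI group in every stage;
delta-alpha is lower in REM and N1, higher in N2, and indistinguishable in
N3 and W, which is exactly the structure the generator plants. `03` recovers
planted respiratory events with RDI correlation r = 0.980 and 85/86 correct
group assignments at the 15/h cutoff; `04` classifies five stages at ~53%
(chance 20%) from window-level MI; `05` finds no coupling-control
correlations beyond the chance rate and a decisive N1 group posterior
(95% HDI [2.88, 4.46] in effect-size units).

The methods vignette (`vignettes/pacfc-methods.Rmd`) documents the signal
model, every tunable parameter, and the numerical design decisions.

## Layout

```
R/                  package code: synthetic PSG generator, EDF/hypnogram IO,
                    filtering + ICA, MI core, respiratory scoring, ML harness,
                    control statistics, pipeline orchestration
analysis/           numbered narrative drivers over the package
tests/testthat/     unit, property and acceptance tests
scripts/acceptance.R
vignettes/          methods vignette
```
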