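---
title: "Benchmarking single- and multi-echo fMRI denoising pipelines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking single- and multi-echo fMRI denoising pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echobench)
```

## The problem

Resting-state fMRI connectivity is contaminated by head motion, widespread
(global) signal deflections, systemic low-frequency oscillations travelling
through the vasculature, and thermal noise.  Dozens of denoising strategies
exist, and they interact: the field's practical question is not which single
step is best, but which *composition* of steps is best, and best *for what*
— data quality and behavioural prediction need not agree.

`echobench` implements a factorial benchmark over 90 pipeline
compositions: two echo handling modes (single-echo, or multi-echo with
T2*-weighted optimal combination), six ICA-based component-rejection
options (none; AROMA-style heuristics; an oracle FIX classifier; ME-ICA
kappa/rho rejection; and the two ME-ICA chains), five nuisance-regression
sets (24P; 24P+8P; 24P+8P+GMSR; 24P+RIPTiDe; 24P+8P+RIPTiDe), and motion
censoring on or off.  SE modes exclude the ME-ICA options, giving
3 x 5 x 2 = 30 single-echo and 6 x 5 x 2 = 60 multi-echo pipelines.
Every pipeline is scored on six data-quality metrics — VE1, DVARS, TSNR,
QC-FC, QC-FC distance dependence, and functional-connectivity inflation
(FCI) — and on kernel-ridge-regression (KRR) prediction of behaviour from
connectivity, and the scores are aggregated by ordinal and
percentage-decrement ranking schemes.

Because suitable multi-echo cohorts with ground truth do not exist, the
package ships a synthetic cohort generator that embodies every signal and
noise process the pipelines target.  All validation rests on it.

## The signal model

Each of `n_elements` spatial elements (gray matter, white matter, CSF,
brain edge) carries a four-echo signal

\[
S_v(t, e) = S0_v\,\bigl(1 + f_v(t)\bigr)\,
            \exp\{-\mathrm{TE}_e\,R2^*_v(t)\} + \varepsilon,
\qquad
R2^*_v(t) = 1/T2^*_v - \delta_v\,n_v(t),
\]

with echo times 12.60/29.23/45.86/62.49 ms, TR 0.91 s and 767 volumes by
default.  Neural activity \(n_v(t)\) enters through \(R2^*\) and is
therefore TE-dependent (BOLD-like); artifacts enter through the
TE-independent multiplier \(f_v(t)\) (S0-like).  This asymmetry is exactly
what ME-ICA's kappa/rho scores test for, so the generator provides ground
truth for component classification by construction.

The artifact multiplier \(f_v(t)\) is the sum of:

* **Motion artifact.** The six rigid-body parameters contain a slow random
  walk, displacement spikes, and a respiratory pseudomotion sinusoid in
  the 0.31–0.41 Hz band.  True framewise displacement (FD) is convolved
  with a spin-history kernel (0.75^k over 8 frames) and multiplied by
  frame-wise lognormal gain jitter; a purely deterministic function of the
  realignment parameters would be absorbed perfectly by 24P regression,
  which real artifacts are not.  Spatially the artifact decays as
  \(\exp(-d/40\,\mathrm{mm})\) from a posterior epicenter (hence
  distance-dependent QC-FC), and is amplified at brain-edge and CSF
  elements.  A lognormal per-subject motion multiplier creates the
  across-subject motion heterogeneity that QC-FC measures.
* **Widespread signal deflection (WSD).** A band-limited (0.01–0.10 Hz)
  common trace whose amplitude ramps linearly over the scan
  (`wsd_ramp`, the source of FCI) with a smooth anterior–posterior gain
  topography.  Real global signal is widespread but not uniform; a
  perfectly uniform deflection would be invisible to the vector-centred
  FC-similarity kernel used for prediction.
* **Lagged sLFO.** A 0.01–0.05 Hz common trace delayed per element by
  lags drawn symmetrically within ±10 s.  The slow band keeps ±10 s
  delays within a fraction of an oscillation period, as for real
  blood-borne oscillations; the antisymmetric lag pairing centres the
  probe's reference arrival time at zero so that per-element lags are
  well defined.

Neural region traces follow a block-modular correlation matrix
(within-module r = 0.4, between 0.05 by default) with per-subject module
strengths, temporally coloured by an AR(1) filter (phi = 0.75) to mimic
hemodynamic low-pass filtering — white traces would be misclassified as
noise by any spectral heuristic, and rightly so.

## Behaviour and the arousal channel

Behavioural scores load on the subject's true connectivity (a random edge
pattern plus a small loading on overall connectivity strength) *and* on an
arousal-like state latent.  The same latent scales the subject's WSD
amplitude.  This gives the widespread signal behaviourally relevant
variance that stationary neural FC does not carry — the mechanism commonly
invoked to explain why global signal removal can cost predictive accuracy
even while it improves every quality metric.  Without such a channel, a
behaviour generated purely from true FC is equally accessible to every
pipeline and the denoising-vs-prediction dissociation dissolves into seed
noise; with it, the dissociation is structural.  `behavior_snr = 0`
replaces the scores with pure noise for null checks.

## Pipeline execution order

For each subject: echo selection (second echo for SE; T2* fit and optimal
combination, with weights \(\mathrm{TE}\,e^{-\mathrm{TE}/T2^*}\), for ME);
a shared mixing matrix (the simulator's ground-truth basis by default, or
a fixed-seed spatial ICA); component rejection by the selected strategies,
merged and removed by nonaggressive OLS filtering; single-step confound
regression (24P always, plus tissue/GM terms and per-frame spike
regressors as requested); lagged sLFO removal for RIPTiDe specs —
estimated from a 24P-only companion series whenever the spec contains 8P,
FIX or ME-ICA; band-pass 0.008–0.08 Hz; removal of censored frames;
gray-matter-probability-weighted parcellation; Pearson correlation and
Fisher z.

Notable numerical choices:

* All filters are zero-phase Butterworth (order 2 prototypes applied
  forward–backward) with reflective padding.
* FD uses the 50 mm rotation-to-displacement convention; censoring flags
  FD > 0.20 mm and bridges clean gaps shorter than 5 frames; exclusion
  uses mean FD > 0.25 mm, >20% of frames over threshold, any FD > 5 mm,
  or >50% flagged.
* T2* fitting uses the longest echo prefix above 3% of the first echo's
  mean (minimum two echoes), a log-linear initialiser, and a Gauss–Newton
  refinement, clipped to [2, 500] ms.  The fit is exact on noise-free
  monoexponential input.
* kappa and rho are amplitude-weighted mean F statistics of one-parameter
  no-intercept fits of per-echo component amplitudes to
  \(\bar S_e\) (S0 model) and \(\bar S_e \mathrm{TE}_e\) (R2* model);
  a component is accepted when kappa >= rho.  F statistics are capped at
  1e8 so the noise-free limit stays finite.
* The AROMA stand-in rejects on csf_fraction > 0.10, high-frequency
  content > 0.35, or (edge_fraction > 0.225 and motion correlation >
  0.45); the published classifier's trained hyperplane is replaced by
  these explicit thresholds, all configurable.
* ICA-FIX is an oracle with configurable TPR/TNR (defaults 0.90/0.90)
  because classifier training data cannot exist for synthetic cohorts.
* sLFO lags are estimated at integer-TR shifts (TR = 0.91 s is finer than
  needed for ±10 s lags) on LFO-band-filtered data, with a positive-peak
  convention and boundary flagging; removal regresses each element on its
  lag-shifted probe over the shift-aligned support.  Because a lag map is
  identified only up to the probe's own arrival time, recovery is
  assessed after centring the map on its mean lag
  (`center_lag_map()`); the centring does not affect removal, which only
  uses relative shifts of a fixed probe.
* Censored frames are both spike-regressed and excluded from FC, FCI and
  window statistics; spike regression alone would leave exact zeros that
  bias correlations.
* Fisher z clips |r| at 1 - 1e-7; FCI splits the retained frames into 20
  equal windows (38 frames at 767 volumes, remainder dropped) and reports
  the OLS slope of window-mean z on window index; windows with fewer than
  10 retained frames are omitted.
* QC-FC uses Spearman correlation with t-approximated p-values and
  Benjamini–Hochberg correction; the ranked QC-FC quantity is median
  absolute rho; QC-FC distance dependence enters composites as a
  magnitude (closeness to zero is best).
* The percentage-decrement scheme is an oriented min–max rescaling to
  [0, 100]; FCI enters rankings as the binary score (1/100 for pipelines
  containing GMSR or RIPTiDe, 2/0 otherwise); ties share average ranks;
  cognition and personality prediction families are ranked independently
  and averaged.
* KRR uses the inter-subject FC-correlation kernel (eigenvalue-clipped to
  PSD), repeated 5-fold CV with an inner 5-fold selection of the ridge
  penalty from 16 log-spaced points in [1e-3, 1e3], mean-FD covariates
  residualised with training-fold betas, and accuracy as the Pearson
  correlation between predictions pooled across folds and the
  residualised scores.  Pooling across folds (rather than per-fold
  correlations) is essential at cohort sizes of a few dozen.
* Missing behaviours (4.64% missing-completely-at-random by default) are
  imputed by single-chain predictive mean matching with 5 donors and 10
  chained passes.

## What the tests show — and what they cannot

The test suite validates exact algebra against brute-force oracles
(nonaggressive filtering, BH step-up, ranking schemes), parameter recovery
(T2* RMSE well under 3 ms at default noise; sLFO lags within one TR;
noise-free KRR r > 0.8 at n = 100 with a permutation null), calibration
(QC-FC false-positive rate near 5% when motion-signal coupling is off),
and directional reproduction on stress cohorts of 30 subjects and 250
frames over ten seeds: GMSR and RIPTiDe collapse VE1 and flatten FCI;
multi-echo optimal combination improves TSNR and DVARS over the second
echo; the denoising-only composite winner always removes widespread
deflections while the prediction-only winner keeps them.

These cohort sizes (problem sizes throughout: 30–100 subjects, 46–140
regions, 150–450 frames) are chosen so the full suite runs on a desktop
in minutes; they are an order of magnitude below real studies, so
percentage-level metric values are not comparable to empirical reports —
only signs, orderings and calibrations are.  The generator also omits
much of real fMRI: no spatial point-spread or k-space effects, no
hemodynamic response function beyond AR(1) colouring, no distortion or
registration error, parcel-level rather than voxel-level granularity, and
an ICA basis that is either exact (ground truth) or a generic fastICA
rather than MELODIC.  Passing tests therefore demonstrate that the
*procedures* are implemented correctly and respond to the targeted
artifact classes in the expected directions, not that any particular
empirical ranking of pipelines on real data would be reproduced.

## Open design points resolved here

* The kappa/rho acceptance threshold is exposed (`ratio_threshold`,
  default 1) rather than reproducing any particular decision tree.
* Exclusion screening and QC-FC use filtered FD by default (configurable).
* The spike-censoring strategy is delta regressors plus downstream frame
  exclusion.
* The sLFO lag-recovery validation runs with the un-lagged WSD switched
  off: in this generative model the WSD and the sLFO are the same class
  of systemic signal, and an un-lagged global trace makes per-element lag
  ground truth ill-defined.  Its amplitude is set to 2% so the
  oscillation is identifiable at the single-subject level.
* `fc_heterogeneity = 0` freezes the cross-subject FC distribution for
  null calibrations where edge-level independence matters.
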