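# echobench

Benchmarking single-echo and multi-echo resting-state fMRI denoising
pipelines on synthetic cohorts with full ground truth.

## The problem

Resting-state functional connectivity (FC) is corrupted by head motion,
widespread (global) signal deflections, systemic low-frequency
oscillations (sLFO) travelling with the blood, and thermal noise.  Many
denoising steps exist — multi-echo optimal combination, ME-ICA kappa/rho
component rejection, AROMA-style heuristics, trained FIX classifiers,
24P/8P/GMSR confound regression, RIPTiDe-style lagged sLFO removal,
motion censoring — and they compose into pipelines whose relative merits
depend on what you optimise: data quality or behavioural prediction.

`echobench` enumerates the full factorial of 90 pipeline compositions
(30 single-echo, 60 multi-echo), executes each on multi-echo data,
scores it on six quality-control metrics

* **VE1** — variance explained by the first principal component of the
  parcellated series (global contamination),
* **DVARS** — RMS frame-to-frame signal change,
* **TSNR** — temporal mean over temporal SD,
* **QC-FC** — across-subject Spearman correlation between each edge's
  Fisher-z FC and mean framewise displacement (plus the percentage of
  edges significant before and after Benjamini–Hochberg correction),
* **QC-FC distance dependence** — correlation of edgewise QC-FC with
  inter-region distance,
* **FCI** — functional-connectivity inflation, the slope of window-mean
  FC over 20 consecutive scan windows,

and on kernel-ridge-regression prediction of behaviour from FC
(covarying mean FD), then aggregates everything with ordinal and
percentage-decrement ranking schemes into denoising, prediction and
overall composites.

Because no public multi-echo benchmark with ground truth exists, the
package includes a synthetic cohort generator
(`cohort_config()`/`generate_cohort()`) producing 4-echo data (TEs
12.60/29.23/45.86/62.49 ms, TR 0.91 s) with monoexponential TE decay,
TE-dependent (BOLD-like) neural fluctuations with modular connectivity,
TE-independent motion artifacts with distance-dependent spatial
structure, a ramped widespread deflection, lagged sLFOs, and behavioural
scores with a known generative model — all exposed as ground truth for
validation.  See the methods vignette
(`vignettes/echobench-methods.Rmd`) for the model and every numerical
choice.

## Worked example

```r
library(echobench)

cfg <- cohort_config(n_subjects = 16, n_elements = 70, n_regions = 46,
                     n_frames = 220, seed = 61)
specs <- list(pipeline_spec("SE", "none",  "24P"),
              pipeline_spec("ME", "none",  "24P+8P+GMSR"),
              pipeline_spec("ME", "AROMA", "24P+RIPTiDe", censor = TRUE))
st <- run_study(cfg, specs, krr_repeats = 1, seed = 2)
st$qcm_table[, c("name", "ve1", "dvars", "tsnr", "fci_slope")]
```

```
                                        name       ve1    dvars      tsnr     fci_slope
1                                SE:MP + 24P 0.5568397 8.649875  57.26767  0.0153861266
2               ME:MP + OC + 24P + 8P + GMSR 0.3354155 4.564553 115.40134 -0.0002190642
3 ME:MP + OC + ICAAROMA + 24P + RIPTiDe + SR 0.3702182 5.046918  94.53708  0.0039562610
```

Read: the multi-echo pipeline with gray-matter signal regression (GMSR)
cuts VE1 by 40% (less global contamination), halves DVARS, doubles TSNR,
and flattens the FCI slope to ~0 compared with the bare single-echo 24P
pipeline; RIPTiDe also suppresses the inflation while keeping more
global signal.  `st$rank_table` holds the per-metric ranks and the three
composites; `top_pipelines(st)` lists the best per echo mode.

A single subject and pipeline:

```r
s  <- generate_subject(cfg, 1)
r  <- run_pipeline(s, pipeline_spec("ME", "MEICA+FIX", "24P+8P+GMSR"))
r$fc$z[1:4, 1:4]          # Fisher-z connectivity
```

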