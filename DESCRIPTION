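Package: echobench
Title: Benchmarking Single- and Multi-Echo fMRI Denoising Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating resting-state fMRI denoising strategies.
    Enumerates and executes a factorial family of 90 single-echo and
    multi-echo denoising pipelines (optimal echo combination, ME-ICA
    kappa/rho component rejection, AROMA-style heuristic and oracle-FIX
    component classification, 24P/8P/GMSR confound regression, motion
    censoring with filtered framewise displacement, and lagged systemic
    low-frequency-oscillation removal), scores each pipeline on six
    data-quality metrics (VE1, DVARS, TSNR, QC-FC, QC-FC distance
    dependence, and functional-connectivity inflation) and on
    kernel-ridge-regression behavioural prediction, and aggregates scores
    with ordinal and percentage-decrement ranking schemes.  Includes a
    synthetic multi-echo cohort generator with full ground truth for
    validation, since suitable public multi-echo benchmark data are scarce.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
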