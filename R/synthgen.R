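#' Configuration for a synthetic multi-echo resting-state cohort
#'
#' Bundles and validates every knob of the cohort generator.  The defaults
#' describe a 4-echo acquisition (TEs 12.60/29.23/45.86/62.49 ms, TR 0.91 s,
#' 767 volumes) with moderate head motion, a widespread signal deflection
#' (WSD) whose amplitude ramps over scan time, lagged systemic low-frequency
#' oscillations (sLFO, lags within +/-10 s), tissue-compartment signals and
#' behavioural scores generated from each subject's true connectivity.
#'
#' Simulation is at parcel-level granularity: `n_elements` spatial elements
#' (gray matter, white matter, CSF and brain-edge compartments) carry the
#' multi-echo signal, and the `n_regions` parcellation is defined over the
#' gray-matter elements.
#'
#' @param n_subjects number of subjects.
#' @param n_elements number of simulated spatial elements.
#' @param n_regions parcellation size (must not exceed the number of
#'   gray-matter elements, about 70% of `n_elements`).
#' @param n_frames volumes per run.
#' @param tr_s repetition time, seconds.
#' @param te_ms echo times, ms, strictly increasing.
#' @param motion_level scale of head motion (0 switches motion off).
#' @param motion_coupling gain of the motion-to-signal artifact pathway;
#'   set to 0 to keep motion in the realignment parameters but out of the
#'   data (used for null calibration of QC-FC).
#' @param wsd_amplitude amplitude of the widespread signal deflection, in
#'   percent signal change per unit trace.
#' @param wsd_ramp per-frame linear growth of the WSD amplitude (drives
#'   functional-connectivity inflation, FCI).
#' @param lfo_amplitude amplitude of the lagged low-frequency oscillation,
#'   percent signal change.
#' @param lfo_lag_range_s half-width of the uniform per-element lag
#'   distribution, seconds.
#' @param pseudomotion_band_hz frequency band of respiratory pseudomotion
#'   injected into the realignment parameters.
#' @param behavior_snr signal-to-noise ratio of the behavioural scores
#'   (0 gives pure-noise behaviour).
#' @param n_behaviors number of behavioural variables (default 7: five
#'   personality domains plus two cognitive scores).
#' @param thermal_sigma additive thermal noise SD, signal units (S0 is of
#'   order 1000).
#' @param missing_rate missing-completely-at-random rate applied to the
#'   cohort behaviour table by [generate_cohort()].
#' @param n_modules number of modules in the block-modular neural
#'   correlation structure.
#' @param fc_heterogeneity scale of cross-subject variation in module
#'   strength (0 gives every subject the same true FC, leaving only
#'   sampling noise -- used for null calibrations).
#' @param seed integer master seed.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 20,
                          n_elements = 150,
                          n_regions = 100,
                          n_frames = 767,
                          tr_s = 0.91,
                          te_ms = c(12.60, 29.23, 45.86, 62.49),
                          motion_level = 1,
                          motion_coupling = 1,
                          wsd_amplitude = 1,
                          wsd_ramp = 0.002,
                          lfo_amplitude = 1,
                          lfo_lag_range_s = 10,
                          pseudomotion_band_hz = c(0.31, 0.41),
                          behavior_snr = 1,
                          n_behaviors = 7,
                          thermal_sigma = 5,
                          missing_rate = 0.0464,
                          n_modules = 4,
                          fc_heterogeneity = 1,
                          seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_elements = as.integer(n_elements),
              n_regions = as.integer(n_regions),
              n_frames = as.integer(n_frames),
              tr_s = tr_s, te_ms = te_ms,
              motion_level = motion_level,
              motion_coupling = motion_coupling,
              wsd_amplitude = wsd_amplitude,
              wsd_ramp = wsd_ramp,
              lfo_amplitude = lfo_amplitude,
              lfo_lag_range_s = lfo_lag_range_s,
              pseudomotion_band_hz = pseudomotion_band_hz,
              behavior_snr = behavior_snr,
              n_behaviors = as.integer(n_behaviors),
              thermal_sigma = thermal_sigma,
              missing_rate = missing_rate,
              n_modules = as.integer(n_modules),
              fc_heterogeneity = fc_heterogeneity,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  stop_if(any(diff(cfg$te_ms) <= 0) || any(cfg$te_ms <= 0),
          "te_ms must be strictly increasing and positive")
  stop_if(cfg$n_frames < 40, "n_frames must be at least 40")
  stop_if(cfg$tr_s <= 0, "tr_s must be positive")
  amps <- c(cfg$motion_level, cfg$motion_coupling, cfg$wsd_amplitude,
            cfg$wsd_ramp, cfg$lfo_amplitude, cfg$behavior_snr,
            cfg$thermal_sigma, cfg$fc_heterogeneity)
  stop_if(any(amps < 0), "amplitude parameters must be nonnegative")
  stop_if(cfg$n_subjects < 1, "n_subjects must be at least 1")
  stop_if(cfg$missing_rate < 0 || cfg$missing_rate >= 1,
          "missing_rate must lie in [0, 1)")
  invisible(cfg)
}

# Per-element BOLD coupling (ms^-1 per unit neural trace): ~1% fractional
# signal change at TE = 30 ms.
BOLD_DELTA <- 3.3e-4
# Motion artifact gain: percent-signal change per mm of framewise displacement
# at the motion epicenter.
MOTION_GAIN <- 0.25
# Spin-history decay of the motion artifact (frames after a displacement);
# the long memory and the frame-wise gain jitter below keep the artifact
# only partially explainable by the instantaneous 24P expansion, as in
# real data.
MOTION_KERNEL <- 0.75^(0:7)
MOTION_JITTER_SD <- 0.3
# Spatial decay length of the motion artifact, mm.
MOTION_LAMBDA <- 40
# Location of the motion epicenter (posterior brain edge), mm.
MOTION_EPICENTER <- c(0, -70, 0)
# Cross-subject SD of the behavioural signal component, used to scale
# behaviour noise from behavior_snr.
BEHAVIOR_SIGNAL_SD <- 0.05
# Loading of the arousal state latent on every behaviour.
AROUSAL_LOADING <- 0.1

# Cohort-level anatomy and fixed cohort parameters; deterministic in
# config$seed and shared by all subjects (same "brain" and atlas).
cohort_anatomy <- function(cfg) {
  with_seed(derive_seed(cfg$seed, 0L), {
    n <- cfg$n_elements
    n_gm <- max(cfg$n_regions, ceiling(0.7 * n))
    stop_if(n_gm > n, "n_elements too small for n_regions gray-matter regions")
    n_rest <- n - n_gm
    n_wm <- floor(0.4 * n_rest)
    n_csf <- floor(0.3 * n_rest)
    n_edge <- n_rest - n_wm - n_csf
    tissue <- c(rep("GM", n_gm), rep("WM", n_wm),
                rep("CSF", n_csf), rep("edge", n_edge))

    # radial placement per compartment: GM in a shell, WM deep, CSF central
    # (ventricles), edge at the brain boundary
    radius <- c(runif(n_gm, 35, 68), runif(n_wm, 5, 40),
                runif(n_csf, 2, 18), runif(n_edge, 68, 75))
    dir <- matrix(rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    coords <- dir * radius

    t2star <- numeric(n)
    t2star[tissue == "GM"] <- rnorm(n_gm, 50, 4)
    t2star[tissue == "WM"] <- rnorm(n_wm, 45, 4)
    t2star[tissue == "CSF"] <- rnorm(n_csf, 90, 8)
    t2star[tissue == "edge"] <- rnorm(n_edge, 35, 6)
    t2star <- pmin(pmax(t2star, 20), 150)

    s0 <- c(rnorm(n_gm, 1000, 40), rnorm(n_wm, 900, 40),
            rnorm(n_csf, 1100, 40), rnorm(n_edge, 500, 40))

    gm_probability <- numeric(n)
    gm_probability[tissue == "GM"] <- runif(n_gm, 0.7, 1)
    gm_probability[tissue == "WM"] <- runif(n_wm, 0, 0.1)
    gm_probability[tissue == "CSF"] <- runif(n_csf, 0, 0.1)
    gm_probability[tissue == "edge"] <- runif(n_edge, 0.1, 0.4)

    region <- rep(NA_integer_, n)
    region[tissue == "GM"] <- rep_len(seq_len(cfg$n_regions), n_gm)

    module <- rep_len(seq_len(cfg$n_modules), cfg$n_regions)

    # per-behaviour edge weights over the upper triangle of the true FC:
    # a random edge pattern plus a loading on overall connectivity
    # strength (behaviours, like general cognition, partly track global
    # FC level)
    n_edge_fc <- n_edges(cfg$n_regions)
    g_load <- 0.05
    behavior_weights <- sqrt(1 - g_load^2) *
      matrix(rnorm(cfg$n_behaviors * n_edge_fc, sd = 1 / sqrt(n_edge_fc)),
             nrow = cfg$n_behaviors) +
      g_load / sqrt(n_edge_fc)

    # per-element gains of the widespread deflection and sLFO pathways;
    # the WSD gain has a smooth anterior-posterior topography (real global
    # signal is widespread but not spatially uniform)
    wsd_gain <- pmax(0.5, 1 + 0.3 * coords[, 2] / 70 + rnorm(n, 0, 0.05))
    # BOLD-weighted systemic signals are weak in CSF
    wsd_gain[tissue == "CSF"] <- 0.4 * wsd_gain[tissue == "CSF"]
    lfo_gain <- runif(n, 0.8, 1.2)
    lfo_gain[tissue == "CSF"] <- 0.4 * lfo_gain[tissue == "CSF"]

    d_epi <- sqrt(colSums((t(coords) - MOTION_EPICENTER)^2))
    motion_gain <- exp(-d_epi / MOTION_LAMBDA)
    motion_gain[tissue == "edge"] <- motion_gain[tissue == "edge"] * 6
    motion_gain[tissue == "CSF"] <- motion_gain[tissue == "CSF"] * 2

    list(tissue = tissue, coords = coords, t2star = t2star, s0 = s0,
         gm_probability = gm_probability, region = region, module = module,
         behavior_weights = behavior_weights, wsd_gain = wsd_gain,
         lfo_gain = lfo_gain, motion_gain = motion_gain, d_epi = d_epi)
  })
}

# Block-modular region correlation with per-module within-block strengths.
modular_fc <- function(module, within, between = 0.05) {
  p <- length(module)
  fc <- matrix(between, p, p)
  for (m in unique(module)) {
    idx <- which(module == m)
    fc[idx, idx] <- within[m]
  }
  diag(fc) <- 1
  fc
}

# Band-limited unit-variance trace by Fourier synthesis: random-phase
# sinusoids with Rayleigh amplitudes on a frequency comb spanning `band`.
# Returns a closure evaluable at arbitrary times (seconds) so the same
# realisation can be sampled at per-element delays.
bandlimited_process <- function(duration_s, band) {
  df <- 1 / max(duration_s, 1 / band[1])
  freqs <- seq(band[1], band[2], by = df)
  amp <- sqrt(-2 * log(runif(length(freqs))))   # Rayleigh
  phase <- runif(length(freqs), 0, 2 * pi)
  norm <- sqrt(sum(amp^2) / 2)
  function(t_s) {
    out <- numeric(length(t_s))
    for (k in seq_along(freqs)) {
      out <- out + amp[k] * sin(2 * pi * freqs[k] * t_s + phase[k])
    }
    out / norm
  }
}

# Band-limited unit-variance trace of length n at sampling rate fs.
bandlimited_trace <- function(n, fs, band) {
  proc <- bandlimited_process(n / fs, band)
  y <- proc((seq_len(n) - 1) / fs)
  s <- sd(y)
  if (s == 0) rep(0, n) else (y - mean(y)) / s
}

#' Generate one synthetic multi-echo subject
#'
#' Draws a full [SubjectRecord]: the element x frame x echo signal array, the
#' six realignment parameters, behavioural scores, and the complete ground
#' truth (true FC, T2*/S0 fields, mixing matrix with component labels,
#' per-element sLFO lags, behaviour weights, true framewise displacement).
#'
#' The signal model is monoexponential in echo time:
#' `S(v,t,e) = S0_v (1 + s0frac_v(t)) exp(-TE_e R2*_v(t)) + noise`, with
#' `R2*_v(t) = 1/T2*_v - delta_v neural_v(t)` so neural fluctuations are
#' TE-dependent (BOLD-like), while motion artifacts, the ramped widespread
#' deflection and the lagged sLFO enter through `s0frac` and are
#' TE-independent (artifact-like).
#'
#' @param config a [cohort_config()].
#' @param subject_index positive integer; combined with `config$seed` it
#'   fully determines the subject.
#' @return a list of class `subject_record` with fields `echo_series`,
#'   `motion`, `behaviors`, `ground_truth`, `subject_id`.
#' @export
generate_subject <- function(config, subject_index) {
  validate_cohort_config(config)
  anat <- cohort_anatomy(config)
  cfg <- config
  n <- cfg$n_elements
  nt <- cfg$n_frames
  ne <- length(cfg$te_ms)
  fs <- 1 / cfg$tr_s

  with_seed(derive_seed(cfg$seed, subject_index), {
    # ---- subject-specific true FC: module strengths vary across subjects
    z_mod <- pmin(pmax(rnorm(cfg$n_modules), -2), 2)
    within <- 0.4 + 0.15 * cfg$fc_heterogeneity * z_mod
    true_fc <- modular_fc(anat$module, within)
    # arousal-like state latent: scales the widespread deflection and
    # contributes to behaviour directly (below), so the WSD carries
    # behaviour-relevant variance that stationary neural FC does not --
    # the mechanism by which global signal removal can cost predictive
    # accuracy
    arousal <- rnorm(1)
    wsd_subj_amp <- min(max(exp(0.5 * arousal), 0.25), 4)

    # ---- neural traces: region level, then propagated to GM elements.
    # AR(1) innovations give the low-frequency-weighted spectrum of
    # hemodynamically filtered activity (white traces would look like
    # noise to spectral heuristics); the same filter per region leaves
    # the cross-region correlation matrix equal to true_fc.
    L <- chol(true_fc)
    innov <- matrix(rnorm(cfg$n_regions * nt), nrow = cfg$n_regions)
    phi <- 0.75
    ar <- t(apply(innov, 1, function(e) {
      as.numeric(stats::filter(e * sqrt(1 - phi^2), phi,
                               method = "recursive"))
    }))
    # stationarise early frames (recursive filter starts from rest)
    ar <- sweep(ar, 2, sqrt(1 - phi^(2 * seq_len(nt))), "/")
    neural_regions <- t(L) %*% ar
    neural <- matrix(0, n, nt)
    gm_idx <- which(anat$tissue == "GM")
    neural[gm_idx, ] <- neural_regions[anat$region[gm_idx], ]
    edge_idx <- which(anat$tissue == "edge")
    if (length(edge_idx) > 0) {
      neural[edge_idx, ] <- 0.3 * neural_regions[
        rep_len(seq_len(cfg$n_regions), length(edge_idx)), ]
    }

    # ---- head motion: slow wander + spikes + respiratory pseudomotion
    params <- matrix(0, nt, 6)
    fd_true <- rep(0, nt)
    if (cfg$motion_level > 0) {
      # across-subject motion heterogeneity (lognormal multiplier)
      m_subj <- cfg$motion_level * exp(rnorm(1, 0, 0.5))
      drift_sd <- m_subj * c(rep(0.02, 3), rep(0.0004, 3))
      drift <- apply(matrix(rnorm(nt * 6), nt, 6) %*% diag(drift_sd),
                     2, cumsum)
      n_spikes <- max(1L, stats::rpois(1, m_subj * 6))
      spike_frames <- sample(5:(nt - 4), n_spikes)
      spikes <- matrix(0, nt, 6)
      for (f in spike_frames) {
        ax <- sample(1:6, 1)
        amp <- m_subj * runif(1, 0.1, 0.45)
        if (ax > 3) amp <- amp / 50  # rotations in radians
        spikes[f:nt, ax] <- spikes[f:nt, ax] + amp * sample(c(-1, 1), 1)
      }
      true_params <- drift + spikes
      fd_true <- fd_from_params(true_params, cfg$tr_s)
      tt <- seq_len(nt) * cfg$tr_s
      f_pm <- mean(cfg$pseudomotion_band_hz)
      pseudo <- m_subj * 0.03 *
        sin(2 * pi * f_pm * tt + runif(1, 0, 2 * pi))
      params <- true_params
      params[, 2] <- params[, 2] + pseudo
      params[, 3] <- params[, 3] + 0.6 * pseudo
    }

    # ---- widespread signal deflection with ramped amplitude
    ramp <- 1 + cfg$wsd_ramp * (seq_len(nt) - 1)
    wsd_course <- if (cfg$wsd_amplitude > 0) {
      bandlimited_trace(nt, fs, c(0.01, 0.10)) * ramp
    } else rep(0, nt)

    # ---- lagged sLFO: oversampled common trace, per-element delay
    # antisymmetric lag pairs (and paired gains below) make the summed
    # probe's effective arrival time exactly zero, so per-element lags are
    # defined relative to a well-centered reference
    half <- runif(ceiling(n / 2), 0, cfg$lfo_lag_range_s)
    lfo_lag <- sample(c(half, -half))[seq_len(n)]
    lfo_mat <- matrix(0, n, nt)
    if (cfg$lfo_amplitude > 0) {
      # slow systemic oscillation: keep the generated spectrum below
      # 0.05 Hz so +/-10 s travel delays stay within a fraction of a
      # period (as for real blood-borne sLFOs)
      proc <- bandlimited_process(nt * cfg$tr_s, c(0.01, 0.05))
      t_frames <- (seq_len(nt) - 1) * cfg$tr_s
      for (v in seq_len(n)) {
        lfo_mat[v, ] <- proc(t_frames - lfo_lag[v])
      }
    }

    # ---- artifact-like S0 fluctuation fraction (percent / 100)
    motion_course <- if (cfg$motion_level > 0 && sd(fd_true) > 0) {
      # spin-history decay with multiplicative gain jitter: a displacement
      # perturbs the signal for several frames, not exactly proportionally
      jit <- fd_true * exp(rnorm(nt, 0, MOTION_JITTER_SD))
      mk <- as.numeric(stats::filter(jit, MOTION_KERNEL, sides = 1))
      mk[is.na(mk)] <- jit[is.na(mk)]
      mk - mean(mk)
    } else rep(0, nt)
    s0frac <- (cfg$motion_coupling * MOTION_GAIN) *
      (anat$motion_gain %o% motion_course) +
      (cfg$wsd_amplitude * wsd_subj_amp * 0.01) *
      (anat$wsd_gain %o% wsd_course) +
      (cfg$lfo_amplitude * 0.01) * (anat$lfo_gain * lfo_mat)

    # ---- ground-truth mixing matrix (frame x component) with labels
    courses <- list()
    labels <- character(0)
    maps <- list()
    for (m in seq_len(cfg$n_modules)) {
      reg_m <- which(anat$module == m)
      courses[[length(courses) + 1]] <- colMeans(neural_regions[reg_m, ,
                                                                drop = FALSE])
      labels <- c(labels, "neural")
      maps[[length(maps) + 1]] <-
        as.numeric(!is.na(anat$region) & anat$region %in% reg_m)
    }
    if (cfg$motion_level > 0 && cfg$motion_coupling > 0 &&
        sd(motion_course) > 0) {
      courses[[length(courses) + 1]] <- motion_course
      labels <- c(labels, "motion")
      maps[[length(maps) + 1]] <- anat$motion_gain
    }
    if (cfg$wsd_amplitude > 0) {
      courses[[length(courses) + 1]] <- wsd_course
      labels <- c(labels, "wsd")
      maps[[length(maps) + 1]] <- anat$wsd_gain
    }
    if (cfg$lfo_amplitude > 0) {
      courses[[length(courses) + 1]] <- colMeans(lfo_mat)
      labels <- c(labels, "lfo")
      maps[[length(maps) + 1]] <- anat$lfo_gain
    }
    mixing <- zscore_cols(do.call(cbind, courses))
    colnames(mixing) <- make.unique(labels)
    spatial_maps <- do.call(cbind, maps)

    # ---- multi-echo signal
    r2star <- 1 / anat$t2star - BOLD_DELTA * (anat$gm_probability * neural)
    base <- anat$s0 * (1 + s0frac)
    signal <- array(0, dim = c(n, nt, ne))
    for (e in seq_len(ne)) {
      signal[, , e] <- base * exp(-cfg$te_ms[e] * r2star)
      if (cfg$thermal_sigma > 0) {
        signal[, , e] <- signal[, , e] +
          matrix(rnorm(n * nt, sd = cfg$thermal_sigma), n, nt)
      }
    }
    stop_if(any(!is.finite(signal)), "internal error: non-finite signal")

    # ---- behaviours from true connectivity
    fc_vec <- upper_tri_vec(true_fc)
    b_signal <- as.numeric(anat$behavior_weights %*% fc_vec) +
      AROUSAL_LOADING * arousal
    behaviors <- if (cfg$behavior_snr <= 0) {
      rnorm(cfg$n_behaviors, sd = BEHAVIOR_SIGNAL_SD)
    } else {
      b_signal + rnorm(cfg$n_behaviors,
                       sd = BEHAVIOR_SIGNAL_SD / cfg$behavior_snr)
    }
    names(behaviors) <- behavior_names(cfg$n_behaviors)

    echo_series <- new_echo_series(signal, cfg$te_ms, cfg$tr_s, anat$tissue,
                                   anat$gm_probability, anat$coords,
                                   region = anat$region)
    motion <- new_motion_params(params, cfg$tr_s)
    gt <- list(true_fc = true_fc, t2star_ms = anat$t2star, s0 = anat$s0,
               mixing_matrix = mixing, component_labels = labels,
               spatial_maps = spatial_maps, lfo_lag_s = lfo_lag,
               behavior_weights = anat$behavior_weights, fd_true = fd_true,
               module = anat$module, arousal = arousal,
               wsd_subject_amp = wsd_subj_amp)
    structure(list(echo_series = echo_series, motion = motion,
                   behaviors = behaviors, ground_truth = gt,
                   subject_id = sprintf("sub-%03d", subject_index)),
              class = "subject_record")
  })
}

behavior_names <- function(n) {
  base <- c("neuroticism", "extraversion", "conscientiousness",
            "agreeableness", "openness", "vocabulary", "matrix_reasoning")
  if (n <= length(base)) base[seq_len(n)] else
    c(base, paste0("behavior_", seq_len(n - length(base))))
}

#' Generate a cohort of synthetic subjects
#'
#' Subjects use independent substreams of the master seed, so any subject can
#' be regenerated in isolation.  A missing-completely-at-random mask at
#' `config$missing_rate` is applied to the pooled behaviour table.
#'
#' @param config a [cohort_config()].
#' @return list of `subject_record` objects; the MCAR mask is reflected in
#'   each subject's `behaviors` (as `NA`).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) generate_subject(config, i))
  if (config$missing_rate > 0) {
    with_seed(derive_seed(config$seed, 999983L), {
      for (i in seq_along(subjects)) {
        miss <- runif(config$n_behaviors) < config$missing_rate
        subjects[[i]]$behaviors[miss] <- NA_real_
      }
    })
  }
  subjects
}

#' Extract the cohort behaviour table
#'
#' @param subjects list of `subject_record`s.
#' @return subject x behaviour numeric matrix (may contain `NA`).
#' @export
cohort_behaviors <- function(subjects) {
  do.call(rbind, lapply(subjects, function(s) s$behaviors))
}

# ---- constructors / validators for the core containers ----------------------

new_echo_series <- function(signal, te_ms, tr_s, tissue, gm_probability,
                            coords_mm, region = NULL) {
  stop_if(any(!is.finite(signal)), "echo series contains non-finite values")
  stop_if(length(dim(signal)) != 3, "signal must be element x frame x echo")
  stop_if(dim(signal)[3] != length(te_ms), "echo count mismatch")
  structure(list(signal = signal, te_ms = te_ms, tr_s = tr_s,
                 tissue = tissue, gm_probability = gm_probability,
                 coords_mm = coords_mm, region = region),
            class = "echo_series")
}

new_motion_params <- function(params, tr_s) {
  params <- as.matrix(params)
  stop_if(ncol(params) != 6, "motion params must have 6 columns")
  stop_if(any(!is.finite(params)), "motion params contain non-finite values")
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(list(params = params, tr_s = tr_s), class = "motion_params")
}

#' Single-echo view of a multi-echo series
#'
#' Returns the echo whose TE is nearest 30 ms (the second echo for the
#' default acquisition), as a frame-indexed element matrix wrapper; this is
#' the series all single-echo pipelines start from.
#'
#' @param series an `echo_series`.
#' @return an `echo_series` with a single echo.
#' @export
se_view <- function(series) {
  e <- which.min(abs(series$te_ms - 30))
  new_echo_series(series$signal[, , e, drop = FALSE], series$te_ms[e],
                  series$tr_s, series$tissue, series$gm_probability,
                  series$coords_mm, series$region)
}

# element x frame matrix of a single-echo series (or a chosen echo)
series_matrix <- function(series, echo = 1L) {
  m <- series$signal[, , echo]
  dim(m) <- dim(series$signal)[1:2]
  m
}
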