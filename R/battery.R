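#' Contrast pipelines used by the directional evaluation battery
#'
#' Six pipelines spanning the decisive contrasts: single-echo vs multi-echo
#' optimal combination, no cleanup vs AROMA, and no widespread-deflection
#' (WSD) removal vs GMSR (with and without ME-ICA/FIX) vs RIPTiDe.
#'
#' @return list of `pipeline_spec`s.
#' @export
battery_pipelines <- function() {
  list(pipeline_spec("SE", "none", "24P"),
       pipeline_spec("ME", "none", "24P"),
       pipeline_spec("ME", "AROMA", "24P"),
       pipeline_spec("ME", "AROMA", "24P+8P+GMSR"),
       pipeline_spec("ME", "MEICA+FIX", "24P+8P+GMSR"),
       pipeline_spec("ME", "none", "24P+RIPTiDe"))
}

#' Directional evaluation battery on stress cohorts
#'
#' Runs the full study (six contrast pipelines, quality metrics, behaviour
#' prediction, rank composites) on one stress cohort per seed and collects
#' the quantities the benchmark turns on: VE1 and FCI with vs without WSD
#' removal, TSNR/DVARS for multi-echo optimal combination vs the second
#' echo, QC-FC summaries, and the identity of the denoising-only and
#' prediction-only composite winners.
#'
#' @param seeds integer vector of cohort seeds.
#' @param n_subjects subjects per cohort.
#' @param n_frames frames per run.
#' @param krr_repeats outer CV repeats for prediction.
#' @param progress print progress.
#' @return list: `per_seed` (data.frame with per-seed winners and metric
#'   contrasts), `qcm_first` (the first seed's full QCM table),
#'   `fci_slopes_first` (per-subject raw-data FCI slopes, first seed).
#' @export
stress_battery <- function(seeds, n_subjects = 30, n_frames = 250,
                           krr_repeats = 2, progress = FALSE) {
  specs <- battery_pipelines()
  names <- vapply(specs, render_name, "")
  has_wsd <- vapply(specs, function(s) {
    grepl("GMSR", s$nuisance, fixed = TRUE) ||
      grepl("RIPTiDe", s$nuisance, fixed = TRUE)
  }, logical(1))
  rows <- vector("list", length(seeds))
  qcm_first <- NULL
  fci_first <- NULL
  for (k in seq_along(seeds)) {
    sd_ <- seeds[k]
    if (progress) message("battery seed ", sd_)
    cfg <- cohort_config(n_subjects = n_subjects, n_frames = n_frames,
                         seed = 200L + sd_)
    st <- run_study(cfg, specs, krr_repeats = krr_repeats, seed = sd_)
    rt <- st$rank_table
    q <- st$qcm_table
    dwin <- which.min(rt$denoise_composite_ordinal)
    pwin <- which.min(rt$prediction_composite_ordinal)
    se_i <- which(names == "SE:MP + 24P")
    me_i <- which(names == "ME:MP + OC + 24P")
    gmsr_i <- which(names == "ME:MP + OC + ICAAROMA + 24P + 8P + GMSR")
    ript_i <- which(names == "ME:MP + OC + 24P + RIPTiDe")
    rows[[k]] <- data.frame(
      seed = sd_,
      denoise_winner = rt$name[dwin],
      denoise_winner_removes_wsd = has_wsd[dwin],
      prediction_winner = rt$name[pwin],
      prediction_winner_keeps_wsd = !has_wsd[pwin],
      ve1_no_removal = q$ve1[me_i], ve1_gmsr = q$ve1[gmsr_i],
      ve1_riptide = q$ve1[ript_i],
      fci_no_removal = q$fci_slope[me_i], fci_gmsr = q$fci_slope[gmsr_i],
      tsnr_se = q$tsnr[se_i], tsnr_me_oc = q$tsnr[me_i],
      dvars_se = q$dvars[se_i], dvars_me_oc = q$dvars[me_i],
      qcfc_med_no_removal = q$qcfc_median_abs[me_i],
      qcfc_med_gmsr = q$qcfc_median_abs[gmsr_i],
      stringsAsFactors = FALSE)
    if (k == 1) {
      qcm_first <- q
      # per-subject FCI slopes of undenoised data for the one-sided test
      co <- generate_cohort(cfg)
      fci_first <- vapply(co, function(s) {
        x <- bandpass(series_matrix(se_view(s$echo_series)),
                      tr_s = cfg$tr_s)
        p <- parcellate(x, membership = s$echo_series$region,
                        gm_probability = s$echo_series$gm_probability,
                        coords_mm = s$echo_series$coords_mm)
        fci(p)$slope
      }, numeric(1))
    }
  }
  list(per_seed = do.call(rbind, rows), qcm_first = qcm_first,
       fci_slopes_first = fci_first)
}

#' QC-FC null calibration cohort
#'
#' Generates a cohort with the motion-to-signal coupling switched off (and
#' no systemic signals or cross-subject FC heterogeneity), computes raw FC
#' matrices and filtered mean FD, and returns the QC-FC summaries.  Under
#' this null the percent of edges significant at p < .05 (uncorrected)
#' should sit near 5%.
#'
#' @param n_subjects subjects (default 50).
#' @param n_regions regions; 46 gives 1,035 edges.
#' @param n_frames frames per run.
#' @param seed cohort seed.
#' @return a `qcfc_result`.
#' @export
qcfc_null_calibration <- function(n_subjects = 50, n_regions = 46,
                                  n_frames = 220, seed = 1L) {
  cfg <- cohort_config(n_subjects = n_subjects, n_elements = n_regions + 24,
                       n_regions = n_regions, n_frames = n_frames,
                       motion_coupling = 0, wsd_amplitude = 0,
                       lfo_amplitude = 0, wsd_ramp = 0,
                       fc_heterogeneity = 0, seed = 300L + seed)
  co <- generate_cohort(cfg)
  fds <- vapply(co, function(s) filtered_fd(s$motion)$mean_fd_mm, 0)
  fcs <- lapply(co, function(s) {
    x <- bandpass(series_matrix(se_view(s$echo_series)), tr_s = cfg$tr_s)
    fc_matrix(parcellate(x, membership = s$echo_series$region,
                         gm_probability = s$echo_series$gm_probability,
                         coords_mm = s$echo_series$coords_mm))
  })
  qcfc(fcs, fds)
}
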