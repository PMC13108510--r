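#' Run the full benchmarking study on a synthetic cohort
#'
#' End-to-end orchestration: generate the cohort, screen subjects on
#' filtered framewise displacement, execute the requested pipelines on
#' every retained subject, compute the six-quality-metric report per
#' pipeline, impute behaviours and evaluate kernel-ridge-regression
#' prediction per pipeline (covarying mean FD), and aggregate everything
#' with the ordinal and percentage-decrement ranking schemes.
#'
#' @param config a [cohort_config()].
#' @param pipelines list of `pipeline_spec`s (default: all 90).
#' @param mixing_source `"ground_truth"` or `"estimated"` mixing matrices.
#' @param krr_repeats outer CV repeats for prediction.
#' @param krr_folds outer CV folds.
#' @param seed seed for ICA/FIX draws, imputation, and CV shuffling.
#' @param include_fci include the binary FCI score in the denoising
#'   composite.
#' @param progress print per-pipeline progress.
#' @return list of class `study_result`: `screening`, `qcm_table`,
#'   `pred_table`, `rank_table`, `pipelines`, `config`, `manifest`.
#' @export
run_study <- function(config, pipelines = enumerate_pipelines(),
                      mixing_source = "ground_truth", krr_repeats = 2,
                      krr_folds = 5, seed = 1L, include_fci = TRUE,
                      progress = FALSE) {
  subjects <- generate_cohort(config)
  fds <- lapply(subjects, function(s) filtered_fd(s$motion))
  screening <- exclusion_screen(fds)
  keep <- which(screening$keep)
  stop_if(length(keep) < 10, "fewer than 10 subjects survive screening")
  subjects <- subjects[keep]
  fds <- fds[keep]
  mean_fd <- vapply(fds, `[[`, 0, "mean_fd_mm")

  behav <- cohort_behaviors(subjects)
  if (any(is.na(behav))) {
    behav <- pmm_impute(behav, seed = seed)
  }

  names <- vapply(pipelines, render_name, "")
  qcm_rows <- vector("list", length(pipelines))
  pred_rows <- vector("list", length(pipelines))
  for (pi in seq_along(pipelines)) {
    spec <- pipelines[[pi]]
    if (progress) message("[", pi, "/", length(pipelines), "] ", names[pi])
    results <- lapply(subjects, run_pipeline, spec = spec,
                      mixing_source = mixing_source, ica_seed = seed)
    rep_q <- qcm_report(results, mean_fd = mean_fd)
    qcm_rows[[pi]] <- data.frame(
      name = names[pi], ve1 = rep_q$ve1, dvars = rep_q$dvars,
      tsnr = rep_q$tsnr, qcfc_median_abs = rep_q$qcfc_median_abs,
      qcfc_pct_sig_unc = rep_q$qcfc_pct_sig_unc,
      qcfc_pct_sig_bh = rep_q$qcfc_pct_sig_bh,
      qcfc_dist_rho = rep_q$qcfc_dist_rho, fci_slope = rep_q$fci_slope,
      stringsAsFactors = FALSE)
    K <- correlation_kernel(lapply(results, `[[`, "fc"))
    acc <- cv_evaluate(K, behav, covariates = mean_fd, folds = krr_folds,
                       repeats = krr_repeats, seed = seed)
    agg <- aggregate_prediction(acc)
    pred_rows[[pi]] <- data.frame(
      name = names[pi], cognition = agg$cognition,
      personality = agg$personality, overall = agg$overall,
      stringsAsFactors = FALSE)
  }
  qcm_table <- do.call(rbind, qcm_rows)
  pred_table <- do.call(rbind, pred_rows)
  rank_table <- composites(qcm_table, pred_table, pipelines,
                           include_fci = include_fci)

  manifest <- list(
    package_version = as.character(utils::packageVersion("echobench")),
    seed = seed, config_seed = config$seed,
    n_subjects_simulated = config$n_subjects,
    n_subjects_retained = length(keep),
    pipelines = names, mixing_source = mixing_source,
    krr = list(folds = krr_folds, repeats = krr_repeats),
    timestamp = format(Sys.time(), tz = "UTC"))

  structure(list(screening = screening, qcm_table = qcm_table,
                 pred_table = pred_table, rank_table = rank_table,
                 pipelines = pipelines, config = config,
                 manifest = manifest),
            class = "study_result")
}

#' Top pipelines from a study result
#'
#' @param study a `study_result`.
#' @param composite one of `"overall"`, `"denoise"`, `"prediction"`.
#' @param scheme `"ordinal"` or `"pct"`.
#' @param n rows to return per echo mode.
#' @return data.frame of the top `n` pipelines per echo mode.
#' @export
top_pipelines <- function(study, composite = c("overall", "denoise",
                                               "prediction"),
                          scheme = c("ordinal", "pct"), n = 10) {
  composite <- match.arg(composite)
  scheme <- match.arg(scheme)
  col <- switch(composite,
                overall = paste0("overall_", scheme),
                denoise = paste0("denoise_composite_", scheme),
                prediction = paste0("prediction_composite_", scheme))
  rt <- study$rank_table
  mode <- substr(rt$name, 1, 2)
  pick <- function(m) {
    sub <- rt[mode == m, c("name", col)]
    ord <- order(sub[[col]], decreasing = (scheme == "pct"))
    head(sub[ord, ], n)
  }
  rbind(pick("ME"), pick("SE"))
}
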