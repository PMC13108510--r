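#' Ordinal ranks (1 = best, ties averaged)
#'
#' @param values numeric metric values, all finite.
#' @param higher_is_better orientation flag.
#' @return numeric ranks.
#' @export
ordinal_rank <- function(values, higher_is_better = TRUE) {
  stop_if(any(!is.finite(values)), "values must be finite")
  stop_if(length(values) < 2, "need at least 2 values")
  if (higher_is_better) rank(-values) else rank(values)
}

#' Binary FCI scores for pipeline specifications
#'
#' Pipelines whose nuisance set removes widespread deflections (GMSR or
#' RIPTiDe) receive ordinal score 1 and percentage score 100; all others
#' receive 2 and 0.
#'
#' @param specs list of `pipeline_spec`s.
#' @return data.frame with columns `ordinal`, `percentage`.
#' @export
fci_binary <- function(specs) {
  removes <- vapply(specs, function(s) {
    grepl("GMSR", s$nuisance, fixed = TRUE) ||
      grepl("RIPTiDe", s$nuisance, fixed = TRUE)
  }, logical(1))
  data.frame(ordinal = ifelse(removes, 1, 2),
             percentage = ifelse(removes, 100, 0))
}

#' Percentage-decrement scores (100 = best)
#'
#' Values are oriented so higher is better, then min-max scaled:
#' `100 (v - worst) / (best - worst)`.
#'
#' @param values numeric metric values.
#' @param higher_is_better orientation flag.
#' @return scores in [0, 100] (all 100, with a warning, when values are
#'   constant).
#' @export
percentage_score <- function(values, higher_is_better = TRUE) {
  stop_if(any(!is.finite(values)), "values must be finite")
  stop_if(length(values) < 2, "need at least 2 values")
  v <- if (higher_is_better) values else -values
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("all values equal; every pipeline scores 100")
    return(rep(100, length(v)))
  }
  100 * (v - rng[1]) / (rng[2] - rng[1])
}

# orientation of each ranked denoising quantity (TRUE = higher is better)
DENOISE_METRICS <- c(ve1 = FALSE, dvars = FALSE, tsnr = TRUE,
                     qcfc = FALSE, qcfc_dist = FALSE)

#' Composite pipeline rankings
#'
#' Builds the two rank-aggregation schemes over a table of per-pipeline
#' metrics: ordinal ranks (1 = best, ties averaged) and percentage
#' decrements (100 = best).  The denoising composite averages the six
#' quality metrics (VE1, DVARS, TSNR, QC-FC as median absolute rho, the
#' magnitude of QC-FC distance dependence, and the binary FCI score); the
#' prediction composite ranks the cognition and personality families
#' independently and averages them; the overall composite is the mean of
#' the two.
#'
#' @param qcm_table data.frame with one row per pipeline and columns
#'   `name`, `ve1`, `dvars`, `tsnr`, `qcfc_median_abs`, `qcfc_dist_rho`.
#' @param pred_table data.frame with columns `name`, `cognition`,
#'   `personality` (mean prediction r per family).
#' @param specs list of `pipeline_spec`s aligned with `qcm_table`.
#' @param include_fci include the binary FCI score in the denoising
#'   composite (switchable for sensitivity analysis).
#' @return data.frame of class `rank_table`: per-metric ranks/scores and
#'   the six composites.
#' @export
composites <- function(qcm_table, pred_table, specs, include_fci = TRUE) {
  needed <- c("name", "ve1", "dvars", "tsnr", "qcfc_median_abs",
              "qcfc_dist_rho")
  missing_cols <- setdiff(needed, names(qcm_table))
  stop_if(length(missing_cols) > 0, "missing metric column(s): ",
          paste(missing_cols, collapse = ", "))
  stop_if(!all(c("name", "cognition", "personality") %in% names(pred_table)),
          "missing prediction column(s)")
  stop_if(!identical(qcm_table$name, pred_table$name),
          "qcm_table and pred_table must list the same pipelines in order")

  vals <- list(ve1 = qcm_table$ve1, dvars = qcm_table$dvars,
               tsnr = qcm_table$tsnr, qcfc = qcm_table$qcfc_median_abs,
               qcfc_dist = abs(qcm_table$qcfc_dist_rho))
  out <- data.frame(name = qcm_table$name, stringsAsFactors = FALSE)
  ord <- list(); pct <- list()
  for (m in names(vals)) {
    ord[[m]] <- ordinal_rank(vals[[m]], DENOISE_METRICS[[m]])
    pct[[m]] <- percentage_score(vals[[m]], DENOISE_METRICS[[m]])
    out[[paste0("rank_", m)]] <- ord[[m]]
    out[[paste0("pct_", m)]] <- pct[[m]]
  }
  fci_scores <- fci_binary(specs)
  out$fci_ordinal <- fci_scores$ordinal
  out$fci_pct <- fci_scores$percentage

  ord_mat <- do.call(cbind, ord)
  pct_mat <- do.call(cbind, pct)
  if (include_fci) {
    ord_mat <- cbind(ord_mat, fci_scores$ordinal)
    pct_mat <- cbind(pct_mat, fci_scores$percentage)
  }
  out$denoise_composite_ordinal <- rowMeans(ord_mat)
  out$denoise_composite_pct <- rowMeans(pct_mat)

  cog_ord <- ordinal_rank(pred_table$cognition, TRUE)
  per_ord <- ordinal_rank(pred_table$personality, TRUE)
  cog_pct <- percentage_score(pred_table$cognition, TRUE)
  per_pct <- percentage_score(pred_table$personality, TRUE)
  out$prediction_composite_ordinal <- (cog_ord + per_ord) / 2
  out$prediction_composite_pct <- (cog_pct + per_pct) / 2

  out$overall_ordinal <- (out$denoise_composite_ordinal +
                            out$prediction_composite_ordinal) / 2
  out$overall_pct <- (out$denoise_composite_pct +
                        out$prediction_composite_pct) / 2
  class(out) <- c("rank_table", "data.frame")
  out
}
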