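#' Variance explained by the first principal component (VE1)
#'
#' First eigenvalue of the region x region correlation matrix divided by the
#' region count; an index of global signal contamination (1 when all
#' regions share one time course, 1/p for independent regions).
#'
#' @param parcels a `parcel_series` (or a plain region x frame matrix).
#' @return fraction in [0, 1].
#' @export
ve1 <- function(parcels) {
  x <- if (inherits(parcels, "parcel_series")) {
    parcels$data[, parcels$retained_frames, drop = FALSE]
  } else as.matrix(parcels)
  stop_if(nrow(x) < 2, "need at least 2 regions")
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance region(s) excluded from VE1")
    x <- x[sds > 0, , drop = FALSE]
  }
  r <- cor(t(x))
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  ev[1] / nrow(r)
}

#' DVARS: RMS frame-to-frame signal change
#'
#' `DVARS_t = sqrt(mean_v (x_{v,t} - x_{v,t-1})^2)` for t >= 2; the subject
#' summary is the mean over frames.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @return list: `dvars` (per frame-pair), `mean` (subject summary).
#' @export
dvars <- function(series) {
  x <- as_element_matrix(series)
  stop_if(ncol(x) < 2, "need at least 2 frames")
  d <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  per_frame <- sqrt(colMeans(d^2))
  list(dvars = per_frame, mean = mean(per_frame))
}

#' Temporal signal-to-noise ratio
#'
#' Per-element temporal mean over temporal SD, averaged over elements;
#' zero-SD elements are excluded and counted.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @return list: `tsnr` (summary mean), `per_element`, `n_excluded`.
#' @export
tsnr <- function(series) {
  x <- as_element_matrix(series)
  stop_if(ncol(x) < 3, "need at least 3 frames")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  ok <- s > 0
  stop_if(!any(ok), "all elements have zero temporal SD")
  ratio <- mu[ok] / s[ok]
  list(tsnr = mean(ratio), per_element = ratio, n_excluded = sum(!ok))
}

# Vectorised Spearman correlation p-values via the t approximation.
spearman_p <- function(rho, n) {
  rho <- pmin(pmax(rho, -1 + 1e-12), 1 - 1e-12)
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(tval), df = n - 2)
}

#' Edgewise QC-FC: motion-connectivity coupling across subjects
#'
#' Per edge, the Spearman correlation between that edge's Fisher-z value
#' and subjects' mean framewise displacement, with summaries: median
#' absolute correlation, percent of edges significant at p < .05
#' uncorrected, and percent significant after Benjamini-Hochberg
#' correction.
#'
#' @param fc_list list of `fc_matrix` objects, one per subject.
#' @param mean_fd numeric per-subject mean FD.
#' @param alpha significance level for the percent-significant summaries.
#' @return list of class `qcfc_result`: `rho` (per edge), `p`,
#'   `median_abs`, `pct_sig_unc`, `pct_sig_bh`, `n_subjects`.
#' @export
qcfc <- function(fc_list, mean_fd, alpha = 0.05) {
  n <- length(fc_list)
  stop_if(n < 10, "need at least 10 subjects")
  stop_if(length(mean_fd) != n, "mean_fd must align with fc_list")
  stop_if(sd(mean_fd) == 0, "mean FD is constant; QC-FC undefined")
  z <- do.call(rbind, lapply(fc_list, function(f) upper_tri_vec(f$z)))
  fd_rank <- rank(mean_fd)
  z_rank <- apply(z, 2, rank)
  rho <- suppressWarnings(as.numeric(cor(z_rank, fd_rank)))
  rho[!is.finite(rho)] <- 0
  p <- spearman_p(rho, n)
  structure(list(rho = rho, p = p,
                 median_abs = median(abs(rho)),
                 pct_sig_unc = 100 * mean(p < alpha),
                 pct_sig_bh = 100 * mean(bh_fdr(p, alpha)),
                 n_subjects = n),
            class = "qcfc_result")
}

#' QC-FC distance dependence
#'
#' Spearman correlation between edgewise QC-FC values and the Euclidean
#' distances between region centroids.
#'
#' @param qcfc_rho per-edge QC-FC values (e.g. `qcfc(...)$rho`).
#' @param centroids_mm region x 3 centroid coordinates.
#' @return Spearman correlation (0, with a warning, when QC-FC is
#'   constant).
#' @export
qcfc_distance <- function(qcfc_rho, centroids_mm) {
  stop_if(is.null(centroids_mm), "centroids are required")
  d <- as.matrix(stats::dist(centroids_mm))
  dvec <- upper_tri_vec(d)
  stop_if(length(dvec) != length(qcfc_rho),
          "edge count does not match centroid count")
  if (sd(qcfc_rho) == 0 || sd(dvec) == 0) {
    warning("degenerate QC-FC or distance vector; returning 0")
    return(0)
  }
  cor(qcfc_rho, dvec, method = "spearman")
}

#' Functional-connectivity inflation (FCI) slope
#'
#' Frames are split into `n_windows` consecutive equal blocks (remainder
#' frames dropped from the tail).  Per window, the mean upper-triangle
#' Fisher-z of the within-window FC is computed over that window's retained
#' frames; the FCI statistic is the OLS slope of window mean z on window
#' index.  Windows with fewer than `min_frames` retained frames are
#' omitted.
#'
#' @param parcels a `parcel_series`.
#' @param n_windows number of windows (default 20).
#' @param min_frames minimum retained frames per usable window.
#' @return list: `slope` (z-units per window), `window_means`, `n_used`.
#' @export
fci <- function(parcels, n_windows = 20, min_frames = 10) {
  nt <- ncol(parcels$data)
  w <- floor(nt / n_windows)
  stop_if(w < 3, "too few frames for the requested window count")
  retained <- parcels$retained_frames
  means <- rep(NA_real_, n_windows)
  for (k in seq_len(n_windows)) {
    frames <- intersect(((k - 1) * w + 1):(k * w), retained)
    if (length(frames) < min_frames) next
    x <- t(parcels$data[, frames, drop = FALSE])
    sds <- apply(x, 2, sd)
    if (sum(sds > 0) < 2) next
    r <- suppressWarnings(cor(x[, sds > 0, drop = FALSE]))
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z <- atanh(r)
    means[k] <- mean(upper_tri_vec(z))
  }
  used <- which(!is.na(means))
  stop_if(length(used) < 3, "fewer than 3 usable windows")
  fit <- lm.fit(cbind(1, used), means[used])
  list(slope = fit$coefficients[2], window_means = means,
       n_used = length(used))
}

#' Benjamini-Hochberg FDR rejection mask
#'
#' Step-up procedure at level `q`: reject the k smallest p-values where k is
#' the largest index with `p_(k) <= k q / m`.
#'
#' @param p p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return logical rejection mask aligned with `p`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  stop_if(any(p < 0 | p > 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH") <= q
}

#' Per-pipeline quality-control report
#'
#' Aggregates the six data-quality metrics over a cohort of pipeline
#' results: mean VE1, mean DVARS, mean TSNR, QC-FC summaries (edge-level
#' across subjects), QC-FC distance dependence, and the mean FCI slope.
#'
#' @param results list of `pipeline_result`s (one subject each, same
#'   pipeline).
#' @param mean_fd per-subject mean (filtered) FD; taken from the results
#'   when omitted.
#' @return list of class `qcm_report` with fields `ve1`, `dvars`, `tsnr`,
#'   `qcfc_median_abs`, `qcfc_pct_sig_unc`, `qcfc_pct_sig_bh`,
#'   `qcfc_dist_rho`, `fci_slope`, `name`.
#' @export
qcm_report <- function(results, mean_fd = NULL) {
  stop_if(length(results) < 2, "need multiple subjects")
  if (is.null(mean_fd)) mean_fd <- vapply(results, `[[`, 0, "mean_fd")
  v <- mean(vapply(results, function(r) ve1(r$parcels), 0))
  d <- mean(vapply(results, function(r) dvars(r$denoised)$mean, 0))
  t <- mean(vapply(results, function(r) tsnr(r$denoised)$tsnr, 0))
  qc <- qcfc(lapply(results, `[[`, "fc"), mean_fd)
  qd <- qcfc_distance(qc$rho, results[[1]]$fc$centroids_mm)
  f <- mean(vapply(results, function(r) fci(r$parcels)$slope, 0))
  structure(list(ve1 = v, dvars = d, tsnr = t,
                 qcfc_median_abs = qc$median_abs,
                 qcfc_pct_sig_unc = qc$pct_sig_unc,
                 qcfc_pct_sig_bh = qc$pct_sig_bh,
                 qcfc_dist_rho = qd, fci_slope = f,
                 name = results[[1]]$name),
            class = "qcm_report")
}
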