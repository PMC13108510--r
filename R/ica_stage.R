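# Accept an element x frame matrix or a single-echo echo_series.
as_element_matrix <- function(x) {
  if (inherits(x, "echo_series")) series_matrix(x) else as.matrix(x)
}

#' Estimate a mixing matrix by spatial ICA (or return the ground truth)
#'
#' A compact fixed-seed FastICA (symmetric decorrelation, tanh contrast) on
#' the spatial dimension after SVD whitening, standing in for a full
#' MELODIC-style decomposition.  With `source = "ground_truth"` the
#' simulator's mixing matrix is returned (column z-scored), mirroring the
#' design in which one shared mixing matrix feeds every ICA-based strategy.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param n_components number of components (must be below the frame count).
#' @param seed integer seed for the ICA rotation initialisation.
#' @param source `"estimated"` or `"ground_truth"`.
#' @param subject the `subject_record` (required for ground-truth mode).
#' @param max_retries re-initialisations attempted on non-convergence.
#' @return list of class `mixing_result`: `mixing` (frame x component,
#'   z-scored columns), `spatial_maps` (element x component), `source`.
#' @export
estimate_components <- function(series, n_components, seed = 1L,
                                source = c("estimated", "ground_truth"),
                                subject = NULL, max_retries = 5L) {
  source <- match.arg(source)
  if (source == "ground_truth") {
    stop_if(is.null(subject), "ground_truth mode requires a subject record")
    gt <- subject$ground_truth
    return(structure(list(mixing = zscore_cols(gt$mixing_matrix),
                          spatial_maps = gt$spatial_maps,
                          labels = gt$component_labels,
                          source = "ground_truth"),
                     class = "mixing_result"))
  }
  x <- as_element_matrix(series)
  nt <- ncol(x)
  stop_if(n_components >= nt, "n_components must be below the frame count")
  xc <- t(x - rowMeans(x))                     # frame x element, centered
  sv <- svd(xc, nu = n_components, nv = n_components)
  k <- n_components
  Z <- t(sv$v[, seq_len(k), drop = FALSE])     # k x element, orthonormal rows

  for (attempt in 0:max_retries) {
    W <- with_seed(derive_seed(seed, attempt), {
      matrix(rnorm(k * k), k, k)
    })
    W <- svd(W)$u %*% t(svd(W)$v)
    ok <- FALSE
    for (it in seq_len(200)) {
      S <- W %*% Z
      G <- tanh(S)
      gp <- rowMeans(1 - G^2)
      W_new <- (G %*% t(Z)) / ncol(Z) - gp * W
      sw <- svd(W_new)
      W_new <- sw$u %*% t(sw$v)
      delta <- max(abs(abs(diag(W_new %*% t(W))) - 1))
      W <- W_new
      if (delta < 1e-7) { ok <- TRUE; break }
    }
    if (ok) break
  }
  if (!ok) stop("spatial ICA failed to converge after ", max_retries + 1,
                " initialisations", call. = FALSE)
  maps <- t(W %*% Z)                           # element x component
  mixing <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k) %*% t(W)         # frame x component
  colnames(mixing) <- paste0("ic", seq_len(k))
  structure(list(mixing = zscore_cols(mixing), spatial_maps = maps,
                 labels = NULL, source = "estimated"),
            class = "mixing_result")
}

#' Heuristic features of mixing-matrix components
#'
#' Computes the features an AROMA-style classifier uses: high-frequency
#' content (median-power frequency over Nyquist), maximum absolute
#' correlation with the 24P realignment-parameter expansion, and the
#' fraction of absolute spatial weight on brain-edge and CSF elements.
#'
#' @param mixing frame x component matrix.
#' @param spatial_maps element x component matrix of spatial weights.
#' @param motion a `motion_params`.
#' @param tissue per-element tissue labels (`GM`, `WM`, `CSF`, `edge`).
#' @return data.frame with columns `hfc`, `max_rp_corr`, `edge_fraction`,
#'   `csf_fraction`.
#' @export
component_features <- function(mixing, spatial_maps, motion, tissue) {
  mixing <- as.matrix(mixing)
  nt <- nrow(mixing)
  stop_if(nrow(motion$params) != nt, "motion frames must match mixing rows")
  stop_if(nrow(as.matrix(spatial_maps)) != length(tissue),
          "spatial maps must align with tissue labels")

  # 24P regressor set for the motion-correlation feature
  rp24 <- do.call(cbind, lapply(1:6, function(j) {
    expansion_terms(motion$params[, j])
  }))
  rp24 <- rp24[, apply(rp24, 2, sd) > 0, drop = FALSE]

  nf <- floor(nt / 2)
  freqs <- seq_len(nf) / nt                    # cycles/frame; Nyquist = 0.5
  hfc <- apply(mixing, 2, function(m) {
    sp <- abs(stats::fft(m - mean(m)))[2:(nf + 1)]^2
    cum <- cumsum(sp) / sum(sp)
    freqs[which(cum >= 0.5)[1]] / 0.5
  })
  max_rp_corr <- if (ncol(rp24) > 0) {
    apply(abs(cor(mixing, rp24)), 1, max)
  } else rep(0, ncol(mixing))

  absw <- abs(as.matrix(spatial_maps))
  tot <- pmax(colSums(absw), 1e-300)
  edge_fraction <- colSums(absw[tissue == "edge", , drop = FALSE]) / tot
  csf_fraction <- colSums(absw[tissue == "CSF", , drop = FALSE]) / tot

  data.frame(hfc = hfc, max_rp_corr = max_rp_corr,
             edge_fraction = edge_fraction, csf_fraction = csf_fraction)
}

#' AROMA-style heuristic component classification
#'
#' A component is rejected when its CSF fraction or high-frequency content
#' exceeds threshold, or when it is simultaneously edge-concentrated and
#' correlated with the realignment parameters.
#'
#' @param features data.frame from [component_features()].
#' @param csf_max,hfc_max,edge_max,rp_max decision thresholds.
#' @return ascending integer indices of rejected components.
#' @export
aroma_classify <- function(features, csf_max = 0.10, hfc_max = 0.35,
                           edge_max = 0.225, rp_max = 0.45) {
  reject <- features$csf_fraction > csf_max |
    features$hfc > hfc_max |
    (features$edge_fraction > edge_max & features$max_rp_corr > rp_max)
  sort(which(reject))
}

#' Oracle FIX-style component classification
#'
#' Emulates a trained classifier with known operating characteristics: each
#' true-noise component is rejected with probability `tpr`, each true-signal
#' component with probability `1 - tnr`.
#'
#' @param labels per-component ground-truth labels; `"neural"` counts as
#'   signal, everything else as noise.
#' @param tpr true positive (noise detection) rate.
#' @param tnr true negative (signal retention) rate.
#' @param seed integer seed.
#' @return ascending integer indices of rejected components.
#' @export
oracle_fix_classify <- function(labels, tpr = 0.90, tnr = 0.90, seed = 1L) {
  stop_if(is.null(labels) || length(labels) == 0,
          "oracle mode requires ground-truth component labels")
  stop_if(tpr < 0 || tpr > 1 || tnr < 0 || tnr > 1,
          "tpr and tnr must lie in [0, 1]")
  is_noise <- labels != "neural"
  with_seed(derive_seed(seed, 13L), {
    u <- runif(length(labels))
    reject <- ifelse(is_noise, u < tpr, u < (1 - tnr))
    sort(which(reject))
  })
}

#' Merge rejection lists
#'
#' @param ... integer vectors of component indices (or a single list of
#'   them).
#' @param n_components optional bound for index validation.
#' @return sorted union with duplicates removed.
#' @export
merge_rejections <- function(..., n_components = NULL) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  all_idx <- sort(unique(unlist(lists)))
  if (length(all_idx) == 0) return(integer(0))
  stop_if(any(all_idx < 1) ||
            (!is.null(n_components) && any(all_idx > n_components)),
          "component index out of range")
  as.integer(all_idx)
}

#' Nonaggressive removal of rejected components
#'
#' Fits the full mixing matrix (plus intercept) to each element's time
#' series by ordinary least squares, then subtracts only the rejected
#' columns' fitted contribution, preserving variance shared with retained
#' components.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param mixing frame x component matrix, full column rank.
#' @param rejected integer indices of components to remove.
#' @return object of the same type as `series` with the noise contribution
#'   removed.
#' @export
nonaggressive_filter <- function(series, mixing, rejected) {
  x <- as_element_matrix(series)
  mixing <- as.matrix(mixing)
  stop_if(nrow(mixing) != ncol(x), "mixing rows must equal frame count")
  rejected <- as.integer(rejected)
  stop_if(length(rejected) > 0 &&
            (any(rejected < 1) || any(rejected > ncol(mixing))),
          "rejected index out of range")
  if (length(rejected) == 0) return(series)
  X <- full_rank_design(mixing)
  B <- solve(crossprod(X), crossprod(X, t(x)))   # (nc+1) x elements
  fitted_noise <- X[, rejected + 1L, drop = FALSE] %*%
    B[rejected + 1L, , drop = FALSE]
  out <- x - t(fitted_noise)
  if (inherits(series, "echo_series")) {
    new_echo_series(array(out, dim = c(dim(out), 1L)), series$te_ms,
                    series$tr_s, series$tissue, series$gm_probability,
                    series$coords_mm, series$region)
  } else out
}
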