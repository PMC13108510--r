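ICA_OPTIONS_SE <- c("none", "AROMA", "FIX")
ICA_OPTIONS_ME <- c("none", "AROMA", "FIX", "MEICA", "MEICA+AROMA",
                    "MEICA+FIX")
NUISANCE_OPTIONS <- c("24P", "24P+8P", "24P+8P+GMSR", "24P+RIPTiDe",
                      "24P+8P+RIPTiDe")

#' Construct a pipeline specification
#'
#' @param echo_mode `"SE"` or `"ME"`.
#' @param ica one of `"none"`, `"AROMA"`, `"FIX"`, `"MEICA"`,
#'   `"MEICA+AROMA"`, `"MEICA+FIX"` (the MEICA variants are ME-only).
#' @param nuisance one of `"24P"`, `"24P+8P"`, `"24P+8P+GMSR"`,
#'   `"24P+RIPTiDe"`, `"24P+8P+RIPTiDe"`.
#' @param censor logical; apply motion censoring (spike regression plus
#'   frame removal).
#' @return list of class `pipeline_spec`.
#' @export
pipeline_spec <- function(echo_mode, ica = "none", nuisance = "24P",
                          censor = FALSE) {
  stop_if(!echo_mode %in% c("SE", "ME"), "echo_mode must be SE or ME")
  valid_ica <- if (echo_mode == "SE") ICA_OPTIONS_SE else ICA_OPTIONS_ME
  stop_if(!ica %in% valid_ica, "invalid ica option '", ica, "' for ",
          echo_mode)
  stop_if(!nuisance %in% NUISANCE_OPTIONS, "invalid nuisance option '",
          nuisance, "'")
  structure(list(echo_mode = echo_mode, ica = ica, nuisance = nuisance,
                 censor = isTRUE(censor)),
            class = "pipeline_spec")
}

#' Enumerate all 90 denoising pipelines
#'
#' Full factorial: 3 ICA options x 5 nuisance sets x 2 censoring states for
#' single-echo (30 pipelines) and 6 x 5 x 2 for multi-echo (60 pipelines),
#' in deterministic order (SE before ME; within mode: ICA, then nuisance,
#' then censoring).
#'
#' @return list of `pipeline_spec`, length 90.
#' @export
enumerate_pipelines <- function() {
  specs <- list()
  for (mode in c("SE", "ME")) {
    icas <- if (mode == "SE") ICA_OPTIONS_SE else ICA_OPTIONS_ME
    for (ica in icas) {
      for (nuis in NUISANCE_OPTIONS) {
        for (cen in c(FALSE, TRUE)) {
          specs[[length(specs) + 1]] <- pipeline_spec(mode, ica, nuis, cen)
        }
      }
    }
  }
  specs
}

#' Render the canonical name of a pipeline
#'
#' Names follow the `"ME:MP + OC + MEICA + ICAFIX + 24P + 8P + GMSR"`
#' convention: echo-mode prefix with minimal preprocessing (`MP`), optimal
#' combination for ME, ICA tokens (MEICA before ICAAROMA/ICAFIX), nuisance
#' tokens in the order 24P, 8P, GMSR/RIPTiDe, and `SR` when censoring is
#' applied.  [parse_name()] inverts it.
#'
#' @param spec a `pipeline_spec`.
#' @return character name.
#' @export
render_name <- function(spec) {
  parts <- if (spec$echo_mode == "ME") c("ME:MP", "OC") else "SE:MP"
  ica_tokens <- switch(spec$ica,
                       none = character(0),
                       AROMA = "ICAAROMA",
                       FIX = "ICAFIX",
                       MEICA = "MEICA",
                       `MEICA+AROMA` = c("MEICA", "ICAAROMA"),
                       `MEICA+FIX` = c("MEICA", "ICAFIX"))
  nuis_tokens <- strsplit(spec$nuisance, "+", fixed = TRUE)[[1]]
  parts <- c(parts, ica_tokens, nuis_tokens)
  if (spec$censor) parts <- c(parts, "SR")
  paste(parts, collapse = " + ")
}

#' Parse a pipeline name back into its specification
#'
#' @param name character name as produced by [render_name()].
#' @return a `pipeline_spec`.
#' @export
parse_name <- function(name) {
  toks <- strsplit(name, " + ", fixed = TRUE)[[1]]
  stop_if(length(toks) < 2, "malformed pipeline name: ", name)
  mode <- switch(toks[1], `SE:MP` = "SE", `ME:MP` = "ME",
                 stop("malformed pipeline name: ", name, call. = FALSE))
  toks <- toks[-1]
  if (mode == "ME") {
    stop_if(length(toks) == 0 || toks[1] != "OC",
            "malformed ME pipeline name: ", name)
    toks <- toks[-1]
  }
  censor <- FALSE
  if (length(toks) > 0 && toks[length(toks)] == "SR") {
    censor <- TRUE
    toks <- toks[-length(toks)]
  }
  ica_toks <- toks[toks %in% c("MEICA", "ICAAROMA", "ICAFIX")]
  nuis_toks <- toks[toks %in% c("24P", "8P", "GMSR", "RIPTiDe")]
  stop_if(length(ica_toks) + length(nuis_toks) != length(toks),
          "malformed pipeline name: ", name)
  ica <- if (length(ica_toks) == 0) "none" else {
    has_meica <- "MEICA" %in% ica_toks
    other <- setdiff(ica_toks, "MEICA")
    other <- if (length(other) == 0) "" else
      switch(other, ICAAROMA = "AROMA", ICAFIX = "FIX")
    if (has_meica && nzchar(other)) paste0("MEICA+", other)
    else if (has_meica) "MEICA" else other
  }
  nuisance <- paste(nuis_toks, collapse = "+")
  pipeline_spec(mode, ica, nuisance, censor)
}

#' Zero-phase band-pass filter
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param low,high band edges, Hz (defaults 0.008 and 0.08).
#' @param tr_s repetition time (taken from an `echo_series` when omitted).
#' @param order Butterworth prototype order.
#' @return same type as `series`, filtered per element.
#' @export
bandpass <- function(series, low = 0.008, high = 0.08, tr_s = NULL,
                     order = 2) {
  x <- as_element_matrix(series)
  if (inherits(series, "echo_series") && is.null(tr_s)) tr_s <- series$tr_s
  stop_if(is.null(tr_s), "need tr_s")
  out <- t(butter_filtfilt(t(x), c(low, high), 1 / tr_s, "pass",
                           order = order))
  if (inherits(series, "echo_series")) {
    new_echo_series(array(out, dim = c(dim(out), 1L)), series$te_ms,
                    series$tr_s, series$tissue, series$gm_probability,
                    series$coords_mm, series$region)
  } else out
}

#' Parcellate an element series with gray-matter-probability weighting
#'
#' Each region's time course is the gray-matter-probability-weighted mean of
#' its member elements, limiting partial-volume contamination.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param membership per-element region index (`NA` for elements outside
#'   the parcellation); taken from an `echo_series` when omitted.
#' @param gm_probability per-element weights.
#' @param coords_mm element x 3 coordinates for region centroids.
#' @param retained_frames integer frame indices to keep downstream
#'   (defaults to all frames).
#' @return list of class `parcel_series`: `data` (region x frame),
#'   `centroids_mm`, `region_names`, `retained_frames`.
#' @export
parcellate <- function(series, membership = NULL, gm_probability = NULL,
                       coords_mm = NULL, retained_frames = NULL) {
  x <- as_element_matrix(series)
  if (inherits(series, "echo_series")) {
    if (is.null(membership)) membership <- series$region
    if (is.null(gm_probability)) gm_probability <- series$gm_probability
    if (is.null(coords_mm)) coords_mm <- series$coords_mm
  }
  stop_if(is.null(membership), "need region membership")
  if (is.null(gm_probability)) gm_probability <- rep(1, nrow(x))
  regions <- sort(unique(membership[!is.na(membership)]))
  data <- matrix(0, length(regions), ncol(x))
  centroids <- matrix(NA_real_, length(regions), 3)
  for (k in seq_along(regions)) {
    idx <- which(!is.na(membership) & membership == regions[k])
    w <- gm_probability[idx]
    stop_if(sum(w) <= 0, "region ", regions[k], " has zero total weight")
    data[k, ] <- as.numeric(crossprod(w, x[idx, , drop = FALSE])) / sum(w)
    if (!is.null(coords_mm)) {
      centroids[k, ] <- colSums(coords_mm[idx, , drop = FALSE] * w) / sum(w)
    }
  }
  if (is.null(retained_frames)) retained_frames <- seq_len(ncol(x))
  structure(list(data = data, centroids_mm = centroids,
                 region_names = paste0("region_", regions),
                 retained_frames = as.integer(retained_frames)),
            class = "parcel_series")
}

#' Fisher-z functional connectivity matrix
#'
#' Pearson product-moment correlations between regional time courses over
#' the retained frames, Fisher r-to-z transformed with |r| clipped at
#' `1 - clip`; the diagonal is set to 0.
#'
#' @param parcels a `parcel_series`.
#' @param clip clipping constant for near-unity correlations.
#' @return list of class `fc_matrix`: `z` (region x region),
#'   `centroids_mm`.
#' @export
fc_matrix <- function(parcels, clip = 1e-7) {
  keep <- parcels$retained_frames
  stop_if(length(keep) < 3, "need at least 3 retained frames")
  x <- t(parcels$data[, keep, drop = FALSE])
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance region(s); their edges are NA")
  }
  r <- suppressWarnings(cor(x))
  r[!is.finite(r)] <- NA
  r <- pmin(pmax(r, -(1 - clip)), 1 - clip)
  z <- atanh(r)
  diag(z) <- 0
  structure(list(z = z, centroids_mm = parcels$centroids_mm),
            class = "fc_matrix")
}

#' Execute one denoising pipeline on one subject
#'
#' Runs the full stage order: echo selection (second echo for SE, T2*
#' fitting plus optimal combination for ME); mixing-matrix acquisition;
#' ICA-based component rejection (ME-ICA kappa/rho, AROMA heuristics,
#' oracle FIX) merged and removed nonaggressively; single-step confound
#' regression (24P, optional 8P/GMSR, spike regressors when censoring);
#' lagged sLFO removal for RIPTiDe specs; band-pass filtering; censored
#' frame removal; gray-matter-weighted parcellation; Pearson FC with
#' Fisher z.
#'
#' @param subject a `subject_record`.
#' @param spec a `pipeline_spec`.
#' @param mixing_source `"ground_truth"` (default, the simulator's shared
#'   mixing matrix) or `"estimated"`.
#' @param n_components components for estimated ICA.
#' @param ica_seed seed for estimated ICA and for the oracle FIX draw.
#' @param fix_tpr,fix_tnr oracle FIX operating characteristics.
#' @param fd_threshold_mm censoring threshold on filtered FD.
#' @param keep_series logical; retain intermediate series in the result.
#' @return list of class `pipeline_result`: `fc`, `parcels`, `denoised`
#'   (element x frame, pre-band-pass), `retained_frames`, `censor`, `spec`,
#'   `name`, `mean_fd`.
#' @export
run_pipeline <- function(subject, spec, mixing_source = "ground_truth",
                         n_components = NULL, ica_seed = 1L,
                         fix_tpr = 0.90, fix_tnr = 0.90,
                         fd_threshold_mm = 0.20, keep_series = TRUE) {
  stage <- "echo selection"
  result <- tryCatch({
    series <- subject$echo_series
    tr_s <- series$tr_s
    if (spec$echo_mode == "ME") {
      t2map <- fit_t2star(series)
      base <- optimal_combine(series, t2map)
    } else {
      base <- se_view(series)
    }
    x <- series_matrix(base)

    stage <- "ICA denoising"
    if (spec$ica != "none") {
      if (is.null(n_components)) {
        n_components <- min(20L, ncol(x) %/% 10L)
      }
      mix <- estimate_components(base, n_components, seed = ica_seed,
                                 source = mixing_source, subject = subject)
      rejections <- list()
      if (spec$ica %in% c("MEICA", "MEICA+AROMA", "MEICA+FIX")) {
        scores <- kappa_rho(series, mix$mixing, oc_series = base)
        rejections$meica <- meica_select(scores)
      }
      if (spec$ica %in% c("AROMA", "MEICA+AROMA")) {
        feats <- component_features(mix$mixing, mix$spatial_maps,
                                    subject$motion, series$tissue)
        rejections$aroma <- aroma_classify(feats)
      }
      if (spec$ica %in% c("FIX", "MEICA+FIX")) {
        stop_if(is.null(mix$labels),
                "oracle FIX needs ground-truth component labels")
        rejections$fix <- oracle_fix_classify(mix$labels, fix_tpr, fix_tnr,
                                              seed = ica_seed)
      }
      rejected <- merge_rejections(rejections,
                                   n_components = ncol(mix$mixing))
      x <- nonaggressive_filter(x, mix$mixing, rejected)
    }

    stage <- "censoring mask"
    fd <- filtered_fd(subject$motion)
    cmask <- if (spec$censor) censor_mask(fd, fd_threshold_mm) else NULL

    stage <- "confound regression"
    wm <- tissue_mean(x, series$tissue, "WM")
    csf <- tissue_mean(x, series$tissue, "CSF")
    gmw <- series$gm_probability * (series$tissue == "GM")
    gm <- as.numeric(crossprod(gmw, x)) / sum(gmw)
    conf <- build_confounds(subject$motion, wm_mean = wm, csf_mean = csf,
                            gm_mean = gm, nuisance = spec$nuisance,
                            censor = cmask)
    mu <- rowMeans(x)
    x_res <- residualize(x, conf) + mu

    stage <- "sLFO removal"
    if (grepl("RIPTiDe", spec$nuisance, fixed = TRUE)) {
      needs_split <- grepl("8P", spec$nuisance, fixed = TRUE) ||
        spec$ica %in% c("FIX", "MEICA", "MEICA+AROMA", "MEICA+FIX")
      x24 <- NULL
      if (needs_split) {
        base24 <- series_matrix(if (spec$echo_mode == "ME")
          optimal_combine(series) else se_view(series))
        conf24 <- build_confounds(subject$motion, nuisance = "24P")
        x24 <- residualize(base24, conf24) + rowMeans(base24)
      }
      x_res <- stage_slfo(x_res, spec, series_24p_only = x24,
                          tissue = series$tissue, gm_weights = gmw,
                          tr_s = tr_s)
    }

    stage <- "band-pass filtering"
    x_bp <- bandpass(x_res, tr_s = tr_s)

    stage <- "parcellation"
    retained <- if (spec$censor) which(!cmask$flagged) else
      seq_len(ncol(x_bp))
    parcels <- parcellate(x_bp, membership = series$region,
                          gm_probability = series$gm_probability,
                          coords_mm = series$coords_mm,
                          retained_frames = retained)

    stage <- "FC estimation"
    fc <- fc_matrix(parcels)

    structure(list(fc = fc, parcels = parcels,
                   denoised = if (keep_series) x_res else NULL,
                   retained_frames = retained, censor = cmask,
                   spec = spec, name = render_name(spec),
                   mean_fd = fd$mean_fd_mm),
              class = "pipeline_result")
  }, error = function(e) {
    stop("pipeline '", render_name(spec), "' failed at stage [", stage,
         "]: ", conditionMessage(e), call. = FALSE)
  })
  result
}
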