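#' sLFO probe regressor
#'
#' Gray-matter-weighted mean time series, band-passed to the low-frequency
#' oscillation band (0.01-0.15 Hz, zero-phase Butterworth order 2) and
#' z-scored.  This is the reference trace that lagged systemic oscillations
#' are estimated against.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param gm_weights per-element gray-matter weights (zeros exclude an
#'   element); taken from the series' `gm_probability` with non-GM elements
#'   zeroed when omitted.
#' @param tissue per-element tissue labels (needed when `series` is a bare
#'   matrix and `gm_weights` is omitted).
#' @param tr_s repetition time (taken from an `echo_series` when omitted).
#' @param band_hz LFO band.
#' @return per-frame z-scored probe (all zeros, with a warning, for
#'   constant input).
#' @export
probe_regressor <- function(series, gm_weights = NULL, tissue = NULL,
                            tr_s = NULL, band_hz = c(0.01, 0.15)) {
  x <- as_element_matrix(series)
  if (inherits(series, "echo_series")) {
    if (is.null(tr_s)) tr_s <- series$tr_s
    if (is.null(tissue)) tissue <- series$tissue
    if (is.null(gm_weights)) {
      gm_weights <- series$gm_probability * (series$tissue == "GM")
    }
  }
  stop_if(is.null(gm_weights) && is.null(tissue),
          "need gm_weights or tissue labels")
  if (is.null(gm_weights)) gm_weights <- as.numeric(tissue == "GM")
  stop_if(is.null(tr_s), "need tr_s")
  stop_if(sum(gm_weights > 0) < 1, "no gray-matter elements")
  gm <- as.numeric(crossprod(gm_weights, x)) / sum(gm_weights)
  if (sd(gm) == 0) {
    warning("constant gray-matter signal; probe is all zeros")
    return(rep(0, length(gm)))
  }
  p <- butter_filtfilt(matrix(gm, ncol = 1), band_hz, 1 / tr_s, "pass",
                       order = 2)[, 1]
  s <- sd(p)
  if (s == 0) {
    warning("probe has no variance after band-passing")
    return(rep(0, length(p)))
  }
  (p - mean(p)) / s
}

# probe delayed by `shift` frames (positive shift = later arrival);
# undefined edge frames are 0 (the probe is zero-mean).
shift_probe <- function(probe, shift) {
  n <- length(probe)
  out <- rep(0, n)
  if (shift >= 0) {
    if (shift < n) out[(shift + 1):n] <- probe[1:(n - shift)]
  } else {
    if (-shift < n) out[1:(n + shift)] <- probe[(1 - shift):n]
  }
  out
}

#' Lagged cross-correlation of element series with the probe
#'
#' Pearson correlation at every integer-TR shift within `+/-max_lag_s`; the
#' lag is the shift maximising the correlation (positive-peak convention).
#' A positive lag means the element's oscillation arrives after the probe.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param probe z-scored per-frame probe from [probe_regressor()].
#' @param tr_s repetition time.
#' @param max_lag_s lag window half-width, seconds.
#' @return data.frame of class `lag_map`: `lag_s`, `peak_r`,
#'   `boundary_flag`, one row per element.
#' @export
crosscorr_lag <- function(series, probe, tr_s = NULL, max_lag_s = 10) {
  x <- as_element_matrix(series)
  if (inherits(series, "echo_series") && is.null(tr_s)) tr_s <- series$tr_s
  stop_if(is.null(tr_s), "need tr_s")
  n <- ncol(x)
  L <- round(max_lag_s / tr_s)
  stop_if(n < 3 * L, "series too short for the requested lag window")
  shifts <- (-L):L
  rmat <- matrix(NA_real_, nrow(x), length(shifts))
  for (k in seq_along(shifts)) {
    s <- shifts[k]
    if (s >= 0) {
      a <- x[, (s + 1):n, drop = FALSE]
      b <- probe[1:(n - s)]
    } else {
      a <- x[, 1:(n + s), drop = FALSE]
      b <- probe[(1 - s):n]
    }
    sda <- apply(a, 1, sd)
    r <- suppressWarnings(as.numeric(cor(t(a), b)))
    r[sda == 0 | !is.finite(r)] <- 0
    rmat[, k] <- r
  }
  best <- max.col(rmat, ties.method = "first")
  out <- data.frame(lag_s = shifts[best] * tr_s,
                    peak_r = rmat[cbind(seq_len(nrow(x)), best)],
                    boundary_flag = abs(shifts[best]) == L)
  class(out) <- c("lag_map", "data.frame")
  out
}

#' Centre a lag map on its mean arrival time
#'
#' A lag map is identified only relative to the probe's own (arbitrary)
#' arrival time: the probe is a weighted sum of delayed copies and carries
#' a phase offset of its own.  Centring on the weighted mean lag removes
#' that offset and leaves the identifiable relative-arrival-time map.
#'
#' @param lagmap `lag_map` from [crosscorr_lag()].
#' @param weights optional per-element weights (e.g. gray-matter
#'   probability); equal weights when omitted.
#' @return the `lag_map` with `lag_s` centred.
#' @export
center_lag_map <- function(lagmap, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(lagmap))
  lagmap$lag_s <- lagmap$lag_s -
    sum(weights * lagmap$lag_s) / sum(weights)
  lagmap
}

#' Remove the lagged sLFO contribution from each element
#'
#' Per element, the series is regressed on an intercept plus the probe
#' shifted by that element's lag (edge frames beyond the shift are excluded
#' from the fit), and the fitted probe contribution is subtracted over the
#' shift-aligned support.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param lagmap `lag_map` from [crosscorr_lag()].
#' @param probe probe regressor the lags were estimated against.
#' @param tr_s repetition time.
#' @return same type as `series` with the sLFO removed.
#' @export
remove_slfo <- function(series, lagmap, probe, tr_s = NULL) {
  x <- as_element_matrix(series)
  if (inherits(series, "echo_series") && is.null(tr_s)) tr_s <- series$tr_s
  stop_if(is.null(tr_s), "need tr_s")
  stop_if(nrow(lagmap) != nrow(x), "lag map not aligned with series")
  if (all(probe == 0)) {
    warning("zero probe; sLFO removal is the identity")
    return(series)
  }
  n <- ncol(x)
  out <- x
  lag_frames <- round(lagmap$lag_s / tr_s)
  for (s in unique(lag_frames)) {
    rows <- which(lag_frames == s)
    p <- shift_probe(probe, s)
    support <- if (s >= 0) (s + 1):n else 1:(n + s)
    ps <- p[support]
    vps <- sum((ps - mean(ps))^2)
    if (vps == 0) next
    xs <- x[rows, support, drop = FALSE]
    b <- as.numeric((xs %*% (ps - mean(ps))) / vps)
    out[rows, support] <- xs - outer(b, ps - mean(ps))
  }
  if (inherits(series, "echo_series")) {
    new_echo_series(array(out, dim = c(dim(out), 1L)), series$te_ms,
                    series$tr_s, series$tissue, series$gm_probability,
                    series$coords_mm, series$region)
  } else out
}

#' sLFO estimation/removal stage with pipeline-dependent sourcing
#'
#' When the pipeline contains 8P, FIX, or ME-ICA (which may remove variance
#' the sLFO estimate needs), the probe and lags are estimated from the
#' companion series that received only 24P regression, and the removal is
#' applied to the fully denoised series; otherwise estimation and removal
#' use the same series.
#'
#' @param series element x frame matrix (the fully denoised data).
#' @param spec a `pipeline_spec`.
#' @param series_24p_only element x frame matrix with only 24P applied
#'   (required when the spec contains 8P, FIX, or MEICA).
#' @param tissue per-element tissue labels.
#' @param gm_weights per-element gray-matter weights.
#' @param tr_s repetition time.
#' @param max_lag_s lag window half-width, seconds.
#' @param band_hz LFO band used for the probe and for pre-filtering the
#'   estimation series before lagged cross-correlation.
#' @return element x frame matrix with the sLFO removed.
#' @export
stage_slfo <- function(series, spec, series_24p_only = NULL, tissue = NULL,
                       gm_weights = NULL, tr_s = NULL, max_lag_s = 10,
                       band_hz = c(0.01, 0.15)) {
  needs_split <- grepl("8P", spec$nuisance, fixed = TRUE) ||
    spec$ica %in% c("FIX", "MEICA", "MEICA+AROMA", "MEICA+FIX")
  est_series <- if (needs_split) {
    stop_if(is.null(series_24p_only),
            "this spec estimates sLFO on the 24P-only series; supply it")
    series_24p_only
  } else series
  est_mat <- as_element_matrix(est_series)
  if (inherits(est_series, "echo_series") && is.null(tr_s)) {
    tr_s <- est_series$tr_s
  }
  probe <- probe_regressor(est_series, gm_weights = gm_weights,
                           tissue = tissue, tr_s = tr_s, band_hz = band_hz)
  if (all(probe == 0)) return(series)
  # lags are estimated on LFO-band-filtered data, where the oscillation is
  # not swamped by broadband signal
  est_bp <- t(butter_filtfilt(t(est_mat), band_hz, 1 / tr_s, "pass",
                              order = 2))
  lagmap <- crosscorr_lag(est_bp, probe, tr_s = tr_s, max_lag_s = max_lag_s)
  remove_slfo(series, lagmap, probe, tr_s = tr_s)
}
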