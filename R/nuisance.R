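#' Erode a 3D binary mask
#'
#' Morphological erosion with a full 3 x 3 x 3 structuring element, iterated.
#' If an iteration would leave fewer than `min_voxels` voxels, that iteration
#' is discarded and the previous mask returned (stop-and-revert rule used
#' for white-matter masks eroded up to five times).
#'
#' @param mask 3D logical array.
#' @param iterations number of erosion passes requested.
#' @param min_voxels minimum voxels a pass must leave (default 5).
#' @return eroded 3D logical array.
#' @export
erode_mask <- function(mask, iterations, min_voxels = 5) {
  stop_if(length(dim(mask)) != 3, "mask must be a 3D array")
  stop_if(sum(mask) == 0, "input mask is empty")
  if (iterations == 0) return(mask)
  erode_once <- function(m) {
    d <- dim(m)
    out <- m
    padded <- array(FALSE, d + 2L)
    padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      out <- out & padded[(2 + dx):(d[1] + 1 + dx),
                          (2 + dy):(d[2] + 1 + dy),
                          (2 + dz):(d[3] + 1 + dz)]
    }
    out
  }
  cur <- mask
  for (i in seq_len(iterations)) {
    nxt <- erode_once(cur)
    if (sum(nxt) < min_voxels) return(cur)
    cur <- nxt
  }
  cur
}

#' Volterra-style expansion of one confound series
#'
#' Returns the series, its square, its backward first difference (first
#' element 0), and the squared difference: the four columns contributed per
#' realignment parameter or tissue-mean signal.
#'
#' @param x numeric per-frame vector (length >= 2).
#' @return frame x 4 matrix with columns `x`, `x2`, `dx`, `dx2`.
#' @export
expansion_terms <- function(x) {
  stop_if(length(x) < 2, "need at least 2 frames")
  dx <- c(0, diff(x))
  cbind(x = x, x2 = x^2, dx = dx, dx2 = dx^2)
}

#' Build a participant-specific confound matrix
#'
#' Always contains the 24P motion set (each of the six realignment
#' parameters with its [expansion_terms()]).  Eight tissue columns (WM and
#' CSF means with the same expansion) are added for 8P, four gray-matter
#' columns for GMSR, and one unit spike column per flagged frame when a
#' censoring mask is supplied.  Constant columns (e.g. from a motionless
#' acquisition) are dropped; genuinely collinear columns raise an error
#' naming them.
#'
#' @param motion a `motion_params`.
#' @param wm_mean,csf_mean,gm_mean per-frame tissue-mean series (only the
#'   ones requested by `nuisance` are used).
#' @param nuisance one of `"24P"`, `"24P+8P"`, `"24P+8P+GMSR"`,
#'   `"24P+RIPTiDe"`, `"24P+8P+RIPTiDe"` (RIPTiDe is handled in a separate
#'   stage; here it only means GMSR is absent).
#' @param censor optional `censor_mask`; flagged frames get spike columns.
#' @return list of class `confound_matrix`: `columns` (frame x regressor,
#'   named), `groups` (named character vector).
#' @export
build_confounds <- function(motion, wm_mean = NULL, csf_mean = NULL,
                            gm_mean = NULL, nuisance = "24P",
                            censor = NULL) {
  nt <- nrow(motion$params)
  parts <- list()
  groups <- character(0)

  for (j in 1:6) {
    e <- expansion_terms(motion$params[, j])
    colnames(e) <- paste0(colnames(motion$params)[j], c("", "_sq",
                                                        "_d", "_dsq"))
    parts[[length(parts) + 1]] <- e
    groups <- c(groups, rep("motion24", 4))
  }
  has_8p <- grepl("8P", nuisance, fixed = TRUE)
  has_gmsr <- grepl("GMSR", nuisance, fixed = TRUE)
  if (has_8p) {
    stop_if(is.null(wm_mean) || is.null(csf_mean),
            "8P requires wm_mean and csf_mean")
    for (nm in c("wm", "csf")) {
      x <- if (nm == "wm") wm_mean else csf_mean
      e <- expansion_terms(x)
      colnames(e) <- paste0(nm, c("", "_sq", "_d", "_dsq"))
      parts[[length(parts) + 1]] <- e
      groups <- c(groups, rep("tissue8", 4))
    }
  }
  if (has_gmsr) {
    stop_if(is.null(gm_mean), "GMSR requires gm_mean")
    e <- expansion_terms(gm_mean)
    colnames(e) <- paste0("gm", c("", "_sq", "_d", "_dsq"))
    parts[[length(parts) + 1]] <- e
    groups <- c(groups, rep("gms4", 4))
  }
  if (!is.null(censor) && censor$n_flagged > 0) {
    flagged <- which(censor$flagged)
    spikes <- matrix(0, nt, length(flagged))
    spikes[cbind(flagged, seq_along(flagged))] <- 1
    colnames(spikes) <- paste0("spike_", flagged)
    parts[[length(parts) + 1]] <- spikes
    groups <- c(groups, rep("spike", length(flagged)))
  }

  cols <- do.call(cbind, parts)
  keep <- apply(cols, 2, sd) > 0 | groups == "spike"
  cols <- cols[, keep, drop = FALSE]
  groups <- groups[keep]

  if (ncol(cols) > 0) {
    q <- qr(cbind(1, scale(cols, scale = FALSE)))
    if (q$rank < ncol(cols) + 1) {
      bad <- colnames(cols)[q$pivot[(q$rank + 1):(ncol(cols) + 1)] - 1L]
      stop("collinear confound column(s): ",
           paste(stats::na.omit(bad), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(columns = cols,
                 groups = setNames(groups, colnames(cols))),
            class = "confound_matrix")
}

#' Residualise a series against a confound matrix
#'
#' Single-step ordinary least squares of every element's time series on the
#' full confound matrix (intercept added internally); returns the residuals.
#'
#' @param series element x frame matrix or single-echo `echo_series`.
#' @param confounds a `confound_matrix` (or plain frame x regressor matrix).
#' @return same type as `series`, residualised.
#' @export
residualize <- function(series, confounds) {
  x <- as_element_matrix(series)
  C <- if (inherits(confounds, "confound_matrix")) confounds$columns
       else as.matrix(confounds)
  stop_if(!is.null(dim(C)) && nrow(C) != ncol(x),
          "confound rows must equal frame count")
  X <- cbind(1, C)
  q <- qr(X)
  stop_if(q$rank < ncol(X), "confound design is rank deficient")
  res <- t(qr.resid(q, t(x)))
  if (inherits(series, "echo_series")) {
    new_echo_series(array(res, dim = c(dim(res), 1L)), series$te_ms,
                    series$tr_s, series$tissue, series$gm_probability,
                    series$coords_mm, series$region)
  } else res
}

# Plain tissue-mean time series from an element x frame matrix.
tissue_mean <- function(x, tissue, which) {
  idx <- tissue == which
  stop_if(!any(idx), "no elements with tissue label ", which)
  colMeans(x[idx, , drop = FALSE])
}
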