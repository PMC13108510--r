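#' Band-stop filter realignment parameters
#'
#' Removes respiratory pseudomotion from the six rigid-body parameters with a
#' zero-phase band-stop Butterworth filter (default band 0.31-0.41 Hz, the
#' respiratory band aliased into fast multiband acquisitions).
#'
#' @param motion a `motion_params` object (frame x 6 matrix + TR).
#' @param band_hz length-2 stop band in Hz; must lie strictly inside
#'   (0, Nyquist).
#' @param order Butterworth prototype order (applied forward-backward).
#' @return a `motion_params` with filtered columns, same length.
#' @export
bandstop_filter_params <- function(motion, band_hz = c(0.31, 0.41),
                                   order = 2) {
  fs <- 1 / motion$tr_s
  filtered <- butter_filtfilt(motion$params, band_hz, fs, "stop",
                              order = order)
  new_motion_params(filtered, motion$tr_s)
}

# FD from a raw frame x 6 parameter matrix (translations mm, rotations rad).
fd_from_params <- function(params, tr_s, head_radius_mm = 50) {
  d <- abs(diff(params))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            head_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Framewise displacement from realignment parameters
#'
#' FD at frame t is the sum of absolute successive differences of the three
#' translations plus the three rotations converted to arc length on a sphere
#' of `head_radius_mm` (default 50 mm).  The first frame is 0 by convention.
#'
#' @param motion a `motion_params` object (typically already band-stop
#'   filtered, see [bandstop_filter_params()]).
#' @param head_radius_mm rotation-to-displacement conversion radius.
#' @param filtered logical flag recorded on the result for bookkeeping.
#' @return list of class `fd_trace`: `fd_mm`, `mean_fd_mm`, `filtered`.
#' @export
compute_fd <- function(motion, head_radius_mm = 50, filtered = FALSE) {
  stop_if(nrow(motion$params) < 2, "need at least 2 frames")
  stop_if(any(!is.finite(motion$params)), "non-finite realignment parameters")
  fd <- fd_from_params(motion$params, motion$tr_s, head_radius_mm)
  structure(list(fd_mm = fd, mean_fd_mm = mean(fd), filtered = filtered),
            class = "fd_trace")
}

#' Filtered framewise displacement
#'
#' Convenience wrapper: band-stop filter the realignment parameters, then
#' compute FD from the filtered columns.
#'
#' @inheritParams compute_fd
#' @inheritParams bandstop_filter_params
#' @return an `fd_trace` with `filtered = TRUE`.
#' @export
filtered_fd <- function(motion, band_hz = c(0.31, 0.41),
                        head_radius_mm = 50) {
  compute_fd(bandstop_filter_params(motion, band_hz), head_radius_mm,
             filtered = TRUE)
}

#' Censoring mask from an FD trace
#'
#' Frames with FD above `threshold_mm` are flagged; any unflagged run of
#' fewer than `bridge_gap` frames lying between two flagged frames is also
#' flagged (short clean gaps are bridged).
#'
#' @param fd an `fd_trace`.
#' @param threshold_mm flagging threshold (default 0.20 mm).
#' @param bridge_gap runs strictly shorter than this many frames are bridged
#'   (default 5).
#' @return list of class `censor_mask`: `flagged` (logical per frame),
#'   `n_flagged`.
#' @export
censor_mask <- function(fd, threshold_mm = 0.20, bridge_gap = 5) {
  stop_if(threshold_mm <= 0, "threshold_mm must be positive")
  flagged <- fd$fd_mm > threshold_mm
  idx <- which(flagged)
  if (length(idx) >= 2) {
    for (k in seq_len(length(idx) - 1)) {
      gap <- idx[k + 1] - idx[k] - 1L
      if (gap > 0 && gap < bridge_gap) {
        flagged[(idx[k] + 1L):(idx[k + 1] - 1L)] <- TRUE
      }
    }
  }
  structure(list(flagged = flagged, n_flagged = sum(flagged)),
            class = "censor_mask")
}

#' Participant-level exclusion screening
#'
#' A subject is dropped if any of: mean FD exceeds `mean_fd_max`; more than
#' `frac_over_max` of frames exceed the censoring threshold; any single FD
#' exceeds `spike_max`; or more than `censor_frac_max` of frames are flagged
#' for censoring (after gap bridging).
#'
#' @param fd_traces list of `fd_trace`s, one per subject.
#' @param masks list of `censor_mask`s aligned with `fd_traces`; computed
#'   from each trace at `fd_threshold_mm` when omitted.
#' @param mean_fd_max mean-FD ceiling, mm (default 0.25).
#' @param frac_over_max maximum tolerated fraction of frames with FD above
#'   `fd_threshold_mm` (default 0.20).
#' @param spike_max single-frame FD ceiling, mm (default 5.00).
#' @param censor_frac_max maximum tolerated flagged fraction (default 0.50).
#' @param fd_threshold_mm frame-level FD threshold (default 0.20 mm).
#' @return data.frame with one row per subject: `keep` plus one logical
#'   column per exclusion reason, and attributes `n_total`, `n_dropped`,
#'   `n_retained`.
#' @export
exclusion_screen <- function(fd_traces, masks = NULL,
                             mean_fd_max = 0.25, frac_over_max = 0.20,
                             spike_max = 5.00, censor_frac_max = 0.50,
                             fd_threshold_mm = 0.20) {
  if (is.null(masks)) {
    masks <- lapply(fd_traces, censor_mask, threshold_mm = fd_threshold_mm)
  }
  stop_if(length(masks) != length(fd_traces),
          "fd_traces and masks must be aligned")
  rows <- lapply(seq_along(fd_traces), function(i) {
    fd <- fd_traces[[i]]$fd_mm
    data.frame(
      subject = i,
      mean_fd = mean(fd) > mean_fd_max,
      frac_over = mean(fd > fd_threshold_mm) > frac_over_max,
      spike = any(fd > spike_max),
      censor_frac = mean(masks[[i]]$flagged) > censor_frac_max)
  })
  out <- do.call(rbind, rows)
  out$keep <- !(out$mean_fd | out$frac_over | out$spike | out$censor_frac)
  attr(out, "n_total") <- nrow(out)
  attr(out, "n_dropped") <- sum(!out$keep)
  attr(out, "n_retained") <- sum(out$keep)
  out
}

#' Mock recruitment roster for screening arithmetic
#'
#' Builds a deterministic roster of FD traces in which exactly `n_total -
#' n_retained` subjects violate at least one exclusion criterion (spread
#' across the four reasons) and the rest are clean, for exercising
#' [exclusion_screen()] end to end.
#'
#' @param n_total recruited sample size (default 418).
#' @param n_retained subjects that must survive screening (default 358).
#' @param n_frames frames per trace.
#' @param tr_s repetition time, seconds.
#' @param seed integer seed.
#' @return list of `fd_trace`s of length `n_total`.
#' @export
mock_screening_roster <- function(n_total = 418, n_retained = 358,
                                  n_frames = 200, tr_s = 0.91, seed = 1L) {
  stop_if(n_retained > n_total, "n_retained cannot exceed n_total")
  n_bad <- n_total - n_retained
  with_seed(derive_seed(seed, 7L), {
    make_trace <- function(fd) {
      structure(list(fd_mm = fd, mean_fd_mm = mean(fd), filtered = TRUE),
                class = "fd_trace")
    }
    clean <- lapply(seq_len(n_retained), function(i) {
      make_trace(c(0, runif(n_frames - 1, 0, 0.12)))
    })
    bad <- lapply(seq_len(n_bad), function(i) {
      base <- c(0, runif(n_frames - 1, 0, 0.12))
      kind <- (i - 1L) %% 4L
      if (kind == 0L) {            # high mean FD
        fd <- base + 0.30
        fd[1] <- 0
      } else if (kind == 1L) {     # >20% of frames above 0.20 mm
        fd <- base
        hot <- sample(2:n_frames, ceiling(0.30 * n_frames))
        fd[hot] <- runif(length(hot), 0.21, 0.24)
      } else if (kind == 2L) {     # a single large spike
        fd <- base
        fd[sample(2:n_frames, 1)] <- runif(1, 5.5, 8)
      } else {                     # >50% of frames flagged after bridging
        fd <- base
        hot <- seq(2, n_frames, by = 3)
        fd[hot] <- runif(length(hot), 0.21, 0.24)
      }
      make_trace(fd)
    })
    c(clean, bad)
  })
}
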