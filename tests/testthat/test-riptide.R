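test_that("the probe is the band-passed z-scored gray-matter mean", {
  nt <- 300
  set.seed(4)
  x <- matrix(rnorm(3 * nt), 3, nt)
  tissue <- c("GM", "WM", "CSF")
  p <- probe_regressor(x, tissue = tissue, tr_s = 0.91)
  # single GM element: probe is that element band-passed and z-scored
  ref <- echobench:::butter_filtfilt(matrix(x[1, ], ncol = 1),
                                     c(0.01, 0.15), 1 / 0.91, "pass",
                                     order = 2)[, 1]
  expect_equal(p, (ref - mean(ref)) / stats::sd(ref), tolerance = 1e-10)
  expect_equal(mean(p), 0, tolerance = 1e-10)
  expect_equal(stats::sd(p), 1, tolerance = 1e-10)
  # white-noise input: probe power concentrated inside the LFO band
  sp <- abs(fft(p))[2:(nt / 2)]^2
  freqs <- (1:(nt / 2 - 1)) / (nt * 0.91)
  inband <- freqs >= 0.008 & freqs <= 0.17
  expect_gt(sum(sp[inband]) / sum(sp), 0.9)
  # constant input: all-zero probe with a warning
  expect_warning(p0 <- probe_regressor(matrix(5, 1, nt), tissue = "GM",
                                       tr_s = 0.91), "constant")
  expect_equal(p0, rep(0, nt))
  expect_error(probe_regressor(x, tissue = c("WM", "WM", "CSF"),
                               tr_s = 0.91), "gray-matter")
})

test_that("lagged cross-correlation recovers constructed shifts", {
  nt <- 400
  set.seed(9)
  probe <- probe_regressor(matrix(rnorm(nt), 1), tissue = "GM", tr_s = 0.91)
  sh <- function(k) echobench:::shift_probe(probe, k)
  x <- rbind(sh(3), probe, sh(-5))
  lm0 <- crosscorr_lag(x, probe, tr_s = 0.91)
  expect_equal(lm0$lag_s, c(3, 0, -5) * 0.91)
  expect_gt(lm0$peak_r[1], 0.9)
  expect_equal(lm0$peak_r[2], 1, tolerance = 1e-10)
  expect_false(any(lm0$boundary_flag))
  # a lag beyond the window pins to the boundary and is flagged
  x15 <- matrix(sh(13), 1)                      # 11.8 s true lag
  lm15 <- crosscorr_lag(x15, probe, tr_s = 0.91)
  expect_true(lm15$boundary_flag[1])
  expect_error(crosscorr_lag(matrix(rnorm(20), 1, 20), probe[1:20],
                             tr_s = 0.91), "short")
})

test_that("sLFO removal strips the lagged probe contribution only", {
  nt <- 400
  set.seed(10)
  probe <- probe_regressor(matrix(rnorm(nt), 1), tissue = "GM", tr_s = 0.91)
  noise <- rnorm(nt, sd = 1)
  y <- 2 * echobench:::shift_probe(probe, 4) + noise
  lagmap <- data.frame(lag_s = 4 * 0.91, peak_r = 0.9,
                       boundary_flag = FALSE)
  out <- remove_slfo(matrix(y, 1), lagmap, probe, tr_s = 0.91)
  support <- 5:nt
  expect_lt(abs(var(out[1, support]) / var(noise[support]) - 1), 0.1)
  # an element orthogonal to every probe shift passes through
  z <- rep(c(1, -1), nt / 2)                    # Nyquist: outside LFO band
  outz <- remove_slfo(matrix(z, 1),
                      data.frame(lag_s = 0, peak_r = 0,
                                 boundary_flag = FALSE),
                      probe, tr_s = 0.91)
  expect_equal(outz[1, ], z, tolerance = 0.05)
})

test_that("per-element lags are recovered within one TR on an sLFO cohort", {
  cfg <- cohort_config(n_subjects = 5, n_elements = 100, n_regions = 70,
                       n_frames = 450, wsd_amplitude = 0, wsd_ramp = 0,
                       lfo_amplitude = 2, seed = 11L)
  errs <- unlist(lapply(1:5, function(i) {
    s <- generate_subject(cfg, i)
    x <- se_view(s$echo_series)
    xm <- x$signal[, , 1]
    p <- probe_regressor(x)
    xf <- t(echobench:::butter_filtfilt(t(xm), c(0.01, 0.15), 1 / 0.91,
                                        "pass", order = 2))
    lm0 <- center_lag_map(crosscorr_lag(xf, p, tr_s = 0.91))
    abs(lm0$lag_s - s$ground_truth$lfo_lag_s)
  }))
  expect_lte(median(errs), 0.91)
})

test_that("the staged removal respects the 24P-only estimation rule", {
  s <- fixture_subject()
  x <- se_view(s$echo_series)$signal[, , 1]
  tissue <- s$echo_series$tissue
  spec_plain <- pipeline_spec("SE", "none", "24P+RIPTiDe")
  spec_split <- pipeline_spec("SE", "FIX", "24P+RIPTiDe")
  # same-series estimation works without the companion series
  out <- stage_slfo(x, spec_plain, tissue = tissue, tr_s = 0.91)
  expect_equal(dim(out), dim(x))
  # 8P/FIX/MEICA specs require the 24P-only series
  expect_error(stage_slfo(x, spec_split, tissue = tissue, tr_s = 0.91),
               "24P-only")
  out2 <- stage_slfo(x, spec_split, series_24p_only = x, tissue = tissue,
                     tr_s = 0.91)
  expect_equal(dim(out2), dim(x))
})

test_that("the stage removes far less variance when no sLFO is present", {
  rel_change <- function(lfo_amp) {
    cfg <- tiny_config(lfo_amplitude = lfo_amp, wsd_amplitude = 0,
                       wsd_ramp = 0, n_frames = 200)
    s <- generate_subject(cfg, 1)
    x <- se_view(s$echo_series)$signal[, , 1]
    out <- stage_slfo(x, pipeline_spec("SE", "none", "24P+RIPTiDe"),
                      tissue = s$echo_series$tissue, tr_s = cfg$tr_s)
    sqrt(sum((out - x)^2) / sum((x - rowMeans(x))^2))
  }
  r0 <- rel_change(0)
  r2 <- rel_change(2)
  # without an sLFO only the probe's shared-variance fraction is touched;
  # with one, the stage removes substantially more
  expect_lt(r0, 0.5)
  expect_gt(r2, r0)
})
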