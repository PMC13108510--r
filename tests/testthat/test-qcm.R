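mk_parcels <- function(d, retained = seq_len(ncol(d))) {
  structure(list(data = d, centroids_mm = matrix(rnorm(3 * nrow(d)),
                                                 nrow(d), 3),
                 region_names = paste0("r", seq_len(nrow(d))),
                 retained_frames = retained), class = "parcel_series")
}

test_that("VE1 spans its analytic anchor cases", {
  base <- rnorm(200)
  p <- mk_parcels(rbind(base, base * 2 + 1, base * -1))
  expect_equal(ve1(p), 1)                        # identical regions
  # two exactly uncorrelated regions: eigenvalues {1, 1} -> 0.5
  a <- rep(c(1, -1), 50); b <- rep(c(1, 1, -1, -1), 25)
  expect_equal(ve1(mk_parcels(rbind(a, b))), 0.5, tolerance = 1e-10)
  set.seed(12)
  noise <- matrix(rnorm(50 * 500), 50, 500)
  expect_lt(ve1(mk_parcels(noise)), 0.1)
})

test_that("DVARS matches its definition and Gaussian expectation", {
  expect_equal(dvars(matrix(3, 5, 10))$mean, 0)
  alt <- matrix(rep(c(1, -1), 10), 4, 20, byrow = TRUE)
  expect_equal(dvars(alt)$dvars, rep(2, 19))
  set.seed(2)
  x <- matrix(rnorm(4000 * 300, sd = 3), 4000, 300)
  expect_lt(abs(dvars(x)$mean / (3 * sqrt(2)) - 1), 0.02)
})

test_that("TSNR is mean over SD with zero-SD elements excluded", {
  x <- rbind(rnorm(500, 100, 10), rep(7, 500))
  out <- tsnr(x)
  expect_equal(out$n_excluded, 1L)
  expect_equal(out$tsnr, mean(x[1, ]) / stats::sd(x[1, ]), tolerance = 1e-12)
  expect_lt(abs(tsnr(matrix(rnorm(2000), 4, 500))$tsnr), 0.2)
  expect_error(tsnr(matrix(1, 3, 10)), "zero temporal SD")
})

test_that("QC-FC recovers a perfect monotone edge and calibrates the null", {
  set.seed(31)
  n_sub <- 30
  fd <- runif(n_sub, 0.05, 0.3)
  fcs <- lapply(seq_len(n_sub), function(i) {
    z <- matrix(rnorm(16, sd = 0.2), 4, 4)
    z <- (z + t(z)) / 2
    z[1, 2] <- z[2, 1] <- fd[i]^3               # monotone in FD
    diag(z) <- 0
    structure(list(z = z, centroids_mm = matrix(rnorm(12), 4, 3)),
              class = "fc_matrix")
  })
  q <- qcfc(fcs, fd)
  expect_equal(max(q$rho), 1)
  expect_equal(which.max(q$rho), 1L)            # edge (1,2) is first
  expect_error(qcfc(fcs, rep(0.1, n_sub)), "constant")
  expect_error(qcfc(fcs[1:5], fd[1:5]), "10")
})

test_that("QC-FC distance dependence matches its exact anchors", {
  cent <- matrix(rnorm(30), 10, 3)
  d <- as.matrix(dist(cent))
  dvec <- d[upper.tri(d)]
  expect_equal(qcfc_distance(-dvec, cent), -1)
  expect_warning(out <- qcfc_distance(rep(0.2, length(dvec)), cent),
                 "degenerate")
  expect_equal(out, 0)
})

test_that("FCI windowing drops the remainder and detects a planted trend", {
  # 767 frames in 20 windows -> 38 frames each, 7 remainder frames unused
  expect_equal(floor(767 / 20), 38)
  set.seed(14)
  nt <- 400
  common <- rnorm(nt) * seq(0.1, 2, length.out = nt)  # growing shared signal
  d <- matrix(rnorm(8 * nt, sd = 1), 8, nt) + rep(common, each = 8)
  out <- fci(mk_parcels(d))
  expect_equal(out$n_used, 20L)
  expect_gt(out$slope, 0)
  # stationary data: slope near zero relative to the trended case
  d0 <- matrix(rnorm(8 * nt), 8, nt) + rep(rnorm(nt), each = 8)
  expect_lt(abs(fci(mk_parcels(d0))$slope), abs(out$slope))
  # censored frames are honoured: windows short of frames are omitted
  out2 <- fci(mk_parcels(d, retained = 41:nt))
  expect_equal(out2$n_used, 18L)
  expect_error(fci(mk_parcels(d[, 1:30])), "window")
})

test_that("BH step-up matches hand cases and an exhaustive oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05), 0.05), rep(TRUE, 5))
  expect_equal(bh_fdr(rep(1, 6)), rep(FALSE, 6))
  expect_equal(bh_fdr(0.04, 0.05), TRUE)
  # oracle: largest k with p_(k) <= k q / m, checked by enumeration
  bh_oracle <- function(p, q) {
    m <- length(p)
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * q / m)
    rej <- rep(FALSE, m)
    if (length(ks) > 0) rej[o[seq_len(max(ks))]] <- TRUE
    rej
  }
  set.seed(77)
  for (i in 1:50) {
    m <- sample(1:10, 1)
    p <- round(runif(m), 3)
    expect_identical(bh_fdr(p, 0.05), bh_oracle(p, 0.05))
    expect_identical(bh_fdr(p, 0.2), bh_oracle(p, 0.2))
  }
})

test_that("the pipeline-level QCM report aggregates all six metrics", {
  cfg <- cohort_config(n_subjects = 12, n_elements = 70, n_regions = 46,
                       n_frames = 220, seed = 41L)
  co <- generate_cohort(cfg)
  res <- lapply(co, run_pipeline, spec = pipeline_spec("SE", "none", "24P"))
  rep_q <- qcm_report(res)
  expect_true(rep_q$ve1 > 0 && rep_q$ve1 < 1)
  expect_gt(rep_q$tsnr, 0)
  expect_gt(rep_q$dvars, 0)
  expect_true(rep_q$qcfc_median_abs >= 0 && rep_q$qcfc_median_abs <= 1)
  expect_true(rep_q$qcfc_pct_sig_unc >= 0 && rep_q$qcfc_pct_sig_unc <= 100)
  expect_true(abs(rep_q$qcfc_dist_rho) <= 1)
  expect_all_finite(rep_q$fci_slope)
})
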