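test_that("ground-truth mixing mode returns the simulator's basis", {
  s <- fixture_subject()
  mix <- estimate_components(NULL, 0, source = "ground_truth", subject = s)
  expect_equal(ncol(mix$mixing), ncol(s$ground_truth$mixing_matrix))
  expect_equal(apply(mix$mixing, 2, stats::sd), rep(1, ncol(mix$mixing)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(mix$labels, s$ground_truth$component_labels)
})

test_that("spatial ICA recovers the subspace of noiseless low-rank data", {
  set.seed(3)
  nt <- 100; n <- 60
  courses <- cbind(sin(2 * pi * (1:nt) / 20), cos(2 * pi * (1:nt) / 7))
  maps <- matrix(rnorm(n * 2), n, 2)
  x <- maps %*% t(courses)                   # element x frame, rank 2
  mix <- estimate_components(x, 2, seed = 1L)
  # principal angle between estimated and true temporal subspaces
  qa <- qr.Q(qr(scale(mix$mixing, scale = FALSE)))
  qb <- qr.Q(qr(scale(courses, scale = FALSE)))
  angle <- acos(min(svd(t(qa) %*% qb)$d))
  expect_lt(angle, 1e-3)
  # fixed seed: identical output
  mix2 <- estimate_components(x, 2, seed = 1L)
  expect_identical(mix, mix2)
  expect_error(estimate_components(x, nt, seed = 1L), "frame count")
})

test_that("component features match their spectral and spatial definitions", {
  nt <- 128
  tr <- 0.91
  motion <- echobench:::new_motion_params(
    cbind(sin((1:nt) / 9), matrix(rnorm(nt * 5, sd = 0.01), nt, 5)), tr)
  nyq <- rep(c(1, -1), nt / 2)                  # pure Nyquist oscillation
  slow <- sin(2 * pi * (1:nt) / 64)
  mixing <- cbind(nyq = nyq, slow = slow, rp = motion$params[, 1])
  tissue <- c(rep("GM", 30), rep("edge", 5), rep("CSF", 5))
  maps <- matrix(0, 40, 3)
  maps[1:30, ] <- 1                             # all weight on GM
  ft <- component_features(mixing, maps, motion, tissue)
  expect_equal(ft$hfc[1], 1)                    # median power at Nyquist
  expect_lt(ft$hfc[2], 0.1)
  expect_equal(ft$max_rp_corr[3], 1)            # equals trans_x
  expect_equal(ft$edge_fraction, rep(0, 3))
  expect_equal(ft$csf_fraction, rep(0, 3))
})

test_that("the AROMA rule set rejects by CSF, spectrum, or edge+motion", {
  ft <- data.frame(hfc = c(0, 0.5, 0, 0, 0),
                   max_rp_corr = c(0, 0, 0.9, 0.9, 0.2),
                   edge_fraction = c(0, 0, 0.3, 0.1, 0.3),
                   csf_fraction = c(0, 0, 0, 0, 0))
  # all-zero features retained; high HFC rejected; edge AND motion rejected;
  # motion without edge retained; edge without motion retained
  expect_equal(aroma_classify(ft), c(2L, 3L))
  ft2 <- data.frame(hfc = 0, max_rp_corr = 0, edge_fraction = 0,
                    csf_fraction = 0.5)
  expect_equal(aroma_classify(ft2), 1L)
})

test_that("AROMA catches the simulator's motion components", {
  cfg <- cohort_config(n_subjects = 5, n_elements = 100, n_regions = 70,
                       n_frames = 250, seed = 11L)
  hits <- vapply(1:5, function(i) {
    s <- generate_subject(cfg, i)
    mix <- estimate_components(NULL, 0, source = "ground_truth", subject = s)
    ft <- component_features(mix$mixing, mix$spatial_maps, s$motion,
                             s$echo_series$tissue)
    rej <- aroma_classify(ft)
    mot <- which(mix$labels == "motion")
    mean(mot %in% rej)
  }, numeric(1))
  expect_gte(mean(hits), 0.7)
})

test_that("the oracle FIX classifier hits its nominal operating point", {
  labels <- rep(c("motion", "neural"), each = 500)
  rej <- oracle_fix_classify(labels, tpr = 1, tnr = 1, seed = 2L)
  expect_equal(rej, 1:500)
  expect_equal(oracle_fix_classify(labels, tpr = 0, tnr = 1, seed = 2L),
               integer(0))
  rej <- oracle_fix_classify(labels, tpr = 0.9, tnr = 0.9, seed = 2L)
  tpr_hat <- mean(1:500 %in% rej)
  tnr_hat <- mean(!(501:1000 %in% rej))
  expect_lt(abs(tpr_hat - 0.9), 0.03)
  expect_lt(abs(tnr_hat - 0.9), 0.03)
  expect_identical(rej, oracle_fix_classify(labels, 0.9, 0.9, seed = 2L))
  expect_error(oracle_fix_classify(character(0)), "labels")
})

test_that("rejection lists merge as a sorted unique union", {
  expect_equal(merge_rejections(c(1L, 3L), c(3L, 5L)), c(1L, 3L, 5L))
  expect_equal(merge_rejections(integer(0), integer(0)), integer(0))
  expect_equal(merge_rejections(2L, integer(0)), 2L)
  expect_error(merge_rejections(c(1L, 9L), n_components = 5), "range")
})

test_that("nonaggressive filtering matches its algebraic contracts", {
  set.seed(8)
  nt <- 50; n <- 30; k <- 5
  mixing <- echobench:::zscore_cols(matrix(rnorm(nt * k), nt, k))
  beta <- matrix(rnorm(n * k), k, n)
  x <- t(mixing %*% beta) + matrix(rnorm(n * nt, sd = 0.1), n, nt)

  # empty rejection is the identity
  expect_identical(nonaggressive_filter(x, mixing, integer(0)), x)

  # orthonormal mixing: nonaggressive equals direct projection removal
  qo <- qr.Q(qr(mixing))
  xq <- x
  out <- nonaggressive_filter(xq, qo, c(1L, 3L))
  xc <- t(scale(t(xq), scale = FALSE))
  brute <- xq - xc %*% qo[, c(1, 3)] %*% t(qo[, c(1, 3)])
  expect_equal(out, brute, tolerance = 1e-8)

  # a series equal to a rejected course is zeroed
  y <- matrix(mixing[, 2], 1)
  out <- nonaggressive_filter(y, mixing, 2L)
  expect_lt(max(abs(out)) / max(abs(y)), 1e-8)

  # idempotence for a fixed rejection set
  once <- nonaggressive_filter(x, mixing, c(2L, 4L))
  twice <- nonaggressive_filter(once, mixing, c(2L, 4L))
  expect_equal(once, twice, tolerance = 1e-10)

  # rejecting everything leaves the OLS residual (intercept included)
  allrej <- nonaggressive_filter(x, mixing, seq_len(k))
  fit <- qr(cbind(1, mixing))
  manual <- t(qr.resid(fit, t(x))) +
    matrix(qr.coef(fit, t(x))[1, ], n, nt)
  expect_equal(allrej, manual, tolerance = 1e-8)

  # filtering never increases per-element variance
  v_before <- apply(x, 1, var)
  v_after <- apply(once, 1, var)
  expect_true(all(v_after <= v_before + 1e-12))
  expect_error(nonaggressive_filter(x, mixing, 99L), "range")
})
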