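make_series <- function(signal, te = c(12.60, 29.23, 45.86, 62.49),
                        tissue = NULL) {
  n <- dim(signal)[1]
  if (is.null(tissue)) tissue <- rep("GM", n)
  echobench:::new_echo_series(signal, te, 0.91, tissue,
                              gm_probability = rep(1, n),
                              coords_mm = matrix(0, n, 3))
}

test_that("T2* fit is exact on noise-free monoexponential data", {
  te <- c(12.60, 29.23, 45.86, 62.49)
  t2_true <- c(40, 25, 60, 90)
  s0_true <- c(1000, 800, 1200, 900)
  nt <- 10
  sig <- array(0, c(4, nt, 4))
  for (e in 1:4) sig[, , e] <- s0_true * exp(-te[e] / t2_true)
  fit <- fit_t2star(make_series(sig))
  expect_equal(fit$t2star_ms, t2_true, tolerance = 1e-8)
  expect_equal(fit$s0, s0_true, tolerance = 1e-8)
  expect_equal(fit$n_echoes_used, rep(4L, 4))
})

test_that("the adaptive echo prefix drops unreliable late echoes", {
  te <- c(12.60, 29.23, 45.86, 62.49)
  nt <- 10
  sig <- array(0, c(2, nt, 4))
  for (e in 1:4) sig[, , e] <- 1000 * exp(-te[e] / 40)
  # element 2's last echo forced below 3% of its first-echo mean
  sig[2, , 4] <- 1000 * 0.01
  fit <- fit_t2star(make_series(sig))
  expect_equal(fit$n_echoes_used, c(4L, 3L))
})

test_that("T2* recovery under default thermal noise is accurate", {
  cfg <- cohort_config(n_subjects = 1, n_elements = 200, n_regions = 140,
                       n_frames = 300, seed = 21L)
  s <- generate_subject(cfg, 1)
  fit <- fit_t2star(s$echo_series)
  rmse <- sqrt(mean((fit$t2star_ms - s$ground_truth$t2star_ms)^2))
  expect_lt(rmse, 3)
})

test_that("optimal combination weights peak at TE nearest T2* and sum to 1", {
  te <- c(12.60, 29.23, 45.86, 62.49)
  # TE * exp(-TE/T2*) is maximised at TE = T2*; for T2* = 30 ms the
  # largest weight falls on the 29.23 ms echo
  w <- te * exp(-te / 30)
  expect_equal(which.max(w), 2L)
  nt <- 50
  sig <- array(rnorm(3 * nt * 4, 1000, 5), c(3, nt, 4))
  t2map <- structure(list(t2star_ms = c(30, 50, 70), s0 = rep(1000, 3),
                          n_echoes_used = rep(4L, 3)), class = "t2star_map")
  oc <- optimal_combine(make_series(sig), t2map)
  expect_equal(dim(oc$signal)[3], 1L)
  # combining four identical echoes returns the common series unchanged
  sig2 <- array(0, c(3, nt, 4))
  base <- matrix(rnorm(3 * nt, 1000, 10), 3, nt)
  for (e in 1:4) sig2[, , e] <- base
  oc2 <- optimal_combine(make_series(sig2), t2map)
  expect_equal(oc2$signal[, , 1], base, tolerance = 1e-12)
  # single-echo input is returned as-is
  se <- make_series(array(base, c(3, nt, 1)), te = 29.23)
  expect_identical(optimal_combine(se), se)
})

test_that("optimally combined data beats the second echo on TSNR", {
  cfg <- cohort_config(n_subjects = 10, n_elements = 80, n_regions = 56,
                       n_frames = 200, seed = 17L)
  wins <- vapply(1:10, function(i) {
    s <- generate_subject(cfg, i)
    oc <- optimal_combine(s$echo_series)
    tsnr(oc)$tsnr >= tsnr(se_view(s$echo_series))$tsnr
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("kappa/rho separates BOLD-like from artifact-like components", {
  # components injected purely through the R2* pathway (noise-free,
  # artifacts off): kappa >> rho, all accepted
  cfg0 <- tiny_config(thermal_sigma = 0, motion_level = 0,
                      wsd_amplitude = 0, lfo_amplitude = 0, wsd_ramp = 0)
  s0 <- generate_subject(cfg0, 1)
  sc0 <- kappa_rho(s0$echo_series, s0$ground_truth$mixing_matrix)
  expect_true(all(s0$ground_truth$component_labels == "neural"))
  expect_true(all(sc0$accepted))
  expect_true(all(sc0$kappa > sc0$rho))

  # under the full noise model, S0-pathway (motion/wsd/lfo) components are
  # rejected and neural components retained
  s <- fixture_subject()
  gt <- s$ground_truth
  sc <- kappa_rho(s$echo_series, gt$mixing_matrix)
  is_neural <- gt$component_labels == "neural"
  expect_true(all(sc$accepted[is_neural]))
  expect_true(all(!sc$accepted[!is_neural]))
  expect_true(all(sc$rho[!is_neural] > sc$kappa[!is_neural]))
  expect_equal(meica_select(sc), which(!is_neural))
})

test_that("kappa/rho is invariant to component time-course scaling", {
  s <- fixture_subject()
  mix <- s$ground_truth$mixing_matrix
  sc1 <- kappa_rho(s$echo_series, mix)
  sc2 <- kappa_rho(s$echo_series, mix %*% diag(c(5, rep(1, ncol(mix) - 1))))
  expect_equal(sc1$kappa, sc2$kappa, tolerance = 1e-8)
  expect_equal(sc1$rho, sc2$rho, tolerance = 1e-8)
})

test_that("the kappa/rho tie falls on the accept side and errors are raised", {
  sc <- data.frame(kappa = c(2, 1, 3), rho = c(2, 2, 1))
  sc$accepted <- sc$kappa >= sc$rho
  expect_equal(meica_select(sc), 2L)
  expect_true(sc$accepted[1])  # kappa/rho exactly 1 is accepted
  s <- fixture_subject()
  mix <- s$ground_truth$mixing_matrix
  bad <- cbind(mix, dup = mix[, 1])
  expect_error(kappa_rho(s$echo_series, bad), "rank deficient")
  expect_error(meica_select(sc[0, ]), "nonempty")
})
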