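test_that("the pipeline factorial enumerates 30 SE and 60 ME configurations", {
  specs <- enumerate_pipelines()
  expect_length(specs, 90)
  modes <- vapply(specs, `[[`, "", "echo_mode")
  expect_equal(sum(modes == "ME"), 60L)
  expect_equal(sum(modes == "SE"), 30L)
  censors <- vapply(specs, `[[`, TRUE, "censor")
  expect_equal(sum(modes == "ME" & !censors), 30L)   # noncensored ME universe
  names <- vapply(specs, render_name, "")
  expect_equal(anyDuplicated(names), 0L)
})

test_that("pipeline names render canonically and parse back", {
  s <- pipeline_spec("ME", "MEICA+FIX", "24P+8P+GMSR", FALSE)
  expect_equal(render_name(s), "ME:MP + OC + MEICA + ICAFIX + 24P + 8P + GMSR")
  expect_equal(render_name(pipeline_spec("SE", "none", "24P")), "SE:MP + 24P")
  expect_equal(render_name(pipeline_spec("SE", "FIX", "24P+RIPTiDe")),
               "SE:MP + ICAFIX + 24P + RIPTiDe")
  expect_equal(render_name(pipeline_spec("ME", "AROMA", "24P+RIPTiDe")),
               "ME:MP + OC + ICAAROMA + 24P + RIPTiDe")
  for (sp in enumerate_pipelines()) {
    expect_identical(parse_name(render_name(sp)), sp)
  }
  expect_error(parse_name("XX:MP + 24P"), "malformed")
  expect_error(pipeline_spec("SE", "MEICA", "24P"), "invalid ica")
})

test_that("the band-pass keeps 0.04 Hz and suppresses 0.2 Hz", {
  tt <- (0:400) * 0.91
  g <- function(f) {
    out <- bandpass(matrix(sin(2 * pi * f * tt), 1), tr_s = 0.91)
    max(abs(out[1, 100:300]))
  }
  expect_gt(g(0.04), 0.95)
  expect_lt(g(0.2), 0.1)
  const <- bandpass(matrix(1, 1, 401), tr_s = 0.91)
  expect_lt(max(abs(const[1, 100:300])), 1e-3)   # DC removed
  expect_error(bandpass(matrix(0, 1, 50), low = 0.5, high = 0.6,
                        tr_s = 0.91), "Nyquist")
})

test_that("parcellation applies gray-matter-probability weighting", {
  x <- rbind(a = c(1, 2), b = c(3, 4))
  p <- parcellate(x, membership = c(1L, 1L), gm_probability = c(0.25, 0.75))
  expect_equal(p$data[1, ], c(2.5, 3.5))
  # all weights equal: plain mean
  p2 <- parcellate(x, membership = c(1L, 1L), gm_probability = c(1, 1))
  expect_equal(p2$data[1, ], c(2, 3))
  # a region carried by one nonzero-weight element is that element
  p3 <- parcellate(x, membership = c(1L, 1L), gm_probability = c(1, 0))
  expect_equal(p3$data[1, ], c(1, 2))
  expect_error(parcellate(x, membership = c(1L, 1L),
                          gm_probability = c(0, 0)), "zero total weight")
})

test_that("FC matrices are clipped, symmetric Fisher-z transforms", {
  set.seed(6)
  d <- rbind(rnorm(100), rnorm(100), rnorm(100))
  d <- rbind(d, d[1, ])                          # duplicated region
  p <- structure(list(data = d, centroids_mm = matrix(0, 4, 3),
                      region_names = paste0("r", 1:4),
                      retained_frames = 1:100), class = "parcel_series")
  fc <- fc_matrix(p)
  expect_equal(fc$z[1, 4], atanh(1 - 1e-7))      # clip rule
  expect_equal(fc$z, t(fc$z))
  expect_equal(diag(fc$z), rep(0, 4))
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # zero-variance region: warning and missing edges
  d2 <- rbind(rnorm(100), rep(1, 100))
  p2 <- structure(list(data = d2, centroids_mm = matrix(0, 2, 3),
                       region_names = c("r1", "r2"),
                       retained_frames = 1:100), class = "parcel_series")
  expect_warning(fc2 <- fc_matrix(p2), "zero-variance")
  expect_true(is.na(fc2$z[1, 2]))
})

test_that("all 90 pipelines run to finite FC on one synthetic subject", {
  cfg <- cohort_config(n_subjects = 1, n_elements = 80, n_regions = 56,
                       n_frames = 220, seed = 3L)
  s <- generate_subject(cfg, 1)
  for (sp in enumerate_pipelines()) {
    r <- run_pipeline(s, sp)
    expect_true(all(is.finite(r$fc$z)), info = r$name)
  }
})

test_that("pipelines hit the clean-data limit and are deterministic", {
  cfg <- cohort_config(n_subjects = 1, n_elements = 80, n_regions = 56,
                       n_frames = 300, motion_level = 0, wsd_amplitude = 0,
                       lfo_amplitude = 0, wsd_ramp = 0, thermal_sigma = 0,
                       seed = 19L)
  s <- generate_subject(cfg, 1)
  r <- run_pipeline(s, pipeline_spec("SE", "none", "24P"))
  raw <- fc_matrix(parcellate(bandpass(se_view(s$echo_series))))
  dz <- abs(r$fc$z - raw$z)[upper.tri(raw$z)]
  expect_lt(mean(dz), 0.05)
  # censor flag is irrelevant on a motionless subject
  rc <- run_pipeline(s, pipeline_spec("SE", "none", "24P", censor = TRUE))
  expect_lt(max(abs(rc$fc$z - r$fc$z)), 1e-10)
  # rerun: bit-identical
  r2 <- run_pipeline(s, pipeline_spec("SE", "none", "24P"))
  expect_identical(r$fc$z, r2$fc$z)
})

test_that("GMSR centres the connectivity distribution under a strong WSD", {
  cfg <- cohort_config(n_subjects = 3, n_elements = 80, n_regions = 56,
                       n_frames = 250, seed = 23L)
  for (i in 1:3) {
    s <- generate_subject(cfg, i)
    z_no <- mean(run_pipeline(s, pipeline_spec("SE", "none", "24P"))$fc$z)
    z_gs <- mean(run_pipeline(s, pipeline_spec("SE", "none",
                                               "24P+8P+GMSR"))$fc$z)
    expect_lt(z_gs, z_no)
  }
})
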