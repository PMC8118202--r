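test_that("IPL thickness model has the required topographic shape", {
  cfg <- phantom_config()
  expect_equal(ipl_thickness_at(cfg, 0), 0)
  expect_equal(ipl_thickness_at(cfg, cfg$ipl_peak_eccentricity_mm),
               cfg$ipl_peak_thickness_um)
  # hand-evaluated piecewise formula beyond the peak: linear decline
  expect_equal(ipl_thickness_at(cfg, 3.75),
               40 - 3 * (3.75 - 1.5), tolerance = 1e-12)
  # rises inside the pit, continuous, non-negative, single broad maximum
  e <- seq(0, 3.75, by = 0.01)
  th <- ipl_thickness_at(cfg, e)
  expect_true(all(th >= 0))
  expect_true(all(diff(th[e <= 1.5]) >= 0))
  expect_true(all(diff(th[e >= 1.5]) <= 0))
  expect_lt(max(abs(diff(th))), 1.5)   # no jumps
  expect_error(ipl_thickness_at(cfg, -0.1), "non-negative")
})

test_that("true profiles are normalized pentalaminar templates", {
  cfg <- phantom_config()
  for (e in c(0.75, 1.2, 2.4, 3.5)) {
    v <- true_profile_at(cfg, e)
    expect_length(v, 101)
    expect_lt(abs(mean(v) - 1), 1e-9)
    ex <- oracle_extrema(v)
    expect_true(ex$valid)
  }
  # S5 peak follows the configured parabola (exactly at the vertex)
  v <- true_profile_at(cfg, 2.4)
  expect_equal(max(v), 1.2, tolerance = 1e-3)
  v075 <- true_profile_at(cfg, 0.75)
  expect_equal(max(v075[1:20]), 1.05, tolerance = 1e-3)
  # hand-evaluated parabola oracle at e = 1.6
  cf <- cfg$s5_contrast_coeffs
  expect_equal(max(true_profile_at(cfg, 1.6)[1:20]),
               cf[1] + cf[2] * 1.6 + cf[3] * 1.6^2, tolerance = 2e-3)
  # S3 peak sits at the midpoint of its stratum fraction
  f <- cfg$stratum_fractions
  s3_center <- (sum(f[1:2]) + f[3] / 2) * 100
  ex <- oracle_extrema(v)
  expect_lt(abs(ex$locations[3] - s3_center), 1)
})

test_that("profile template survives jittered fractions and eccentricities", {
  set.seed(91)
  for (rep in 1:25) {
    f <- pmax(c(0.18, 0.17, 0.24, 0.23, 0.18) + rnorm(5, 0, 0.012), 0.05)
    cfg <- phantom_config(stratum_fractions = f / sum(f))
    v <- true_profile_at(cfg, runif(1, 0, 3.75))
    expect_lt(abs(mean(v) - 1), 1e-9)
    expect_true(oracle_extrema(v)$valid)
  }
})

test_that("rendering is deterministic and respects the seed", {
  cfg <- small_config(n_frames = 3)
  a <- render_frame_stack(cfg, seed = 77)
  b <- render_frame_stack(cfg, seed = 77)
  expect_identical(a$stack$frames, b$stack$frames)
  expect_identical(a$truth, b$truth)
  c <- render_frame_stack(cfg, seed = 78)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("single-frame speckle has unit contrast in a homogeneous layer", {
  cfg <- small_config(n_frames = 1, additive_noise_sd = 0,
                      additive_noise_mean = 0, axial_jitter_sd_px = 0)
  rs <- render_frame_stack(cfg, seed = 12)
  # ONL interior rows (flat layer between OPL and IS/OS), px size 2 um
  rows <- 90:105
  vals <- rs$stack$frames[rows, , 1]
  expect_lt(abs(stats::sd(vals) / mean(vals) - 1), 0.05)
})

test_that("frame-mean converges to the mean reflectance image", {
  cfg <- small_config(n_frames = 24, additive_noise_sd = 0,
                      additive_noise_mean = 0, axial_jitter_sd_px = 0)
  rs <- render_frame_stack(cfg, seed = 13)
  ref <- render_frame_stack(small_noisefree(), seed = 13)
  avg <- apply(rs$stack$frames, c(1, 2), mean)
  rel <- abs(avg - ref$stack$frames[, , 1]) /
    pmax(ref$stack$frames[, , 1], 0.1)
  expect_lt(mean(rel), 2 / sqrt(24))
})

test_that("speckle contrast falls as one over sqrt of frame count", {
  rows <- 90:105
  for (seed in c(1, 2)) {
    contrasts <- vapply(c(1, 4, 16), function(nf) {
      cfg <- small_config(n_frames = nf, additive_noise_sd = 0,
                          additive_noise_mean = 0, axial_jitter_sd_px = 0)
      rs <- render_frame_stack(cfg, seed = seed)
      avg <- apply(rs$stack$frames[rows, , , drop = FALSE], c(1, 2), mean)
      stats::sd(avg) / mean(avg)
    }, numeric(1))
    expect_lt(max(abs(contrasts * sqrt(c(1, 4, 16)) - 1)), 0.2)
  }
})

test_that("cohort rendering honors the design and subject distributions", {
  cfg <- small_noisefree()
  co <- render_cohort(cfg, n_subjects = 2, n_angles = 3, seed = 5)
  expect_length(co$stacks, 6)
  expect_equal(nrow(co$manifest), 6)
  expect_equal(unique(co$manifest$scan_angle_deg), c(0, 30, 60))
  expect_error(render_cohort(cfg, n_subjects = 2, n_angles = 7), "180")
  # zero between-subject SD: identical anatomy
  co0 <- render_cohort(cfg, n_subjects = 3, n_angles = 1,
                       subject_sd = list(ipl_peak_thickness_um = 0,
                                         s5_plateau = 0, s5_vertex_mm = 0,
                                         fraction_sd = 0),
                       fixation_sd_mm = 0, seed = 6)
  expect_equal(length(unique(co0$subjects$ipl_peak_thickness_um)), 1)
  expect_equal(unique(co0$manifest$fixation_offset_mm), 0)
  # zero fixation error: foveola at the lateral center of the truth
  expect_lt(abs(co0$truths[[1]]$eccentricity_mm[250]), 0.01)
})

test_that("the angular conversion constant maps 1.5 degrees to 450 um", {
  expect_equal(degrees_to_microns(1.5), 450)
  cfg <- phantom_config()
  expect_equal(degrees_to_microns(1.5, cfg$microns_per_degree), 450)
})

test_that("invalid phantom configurations are rejected", {
  expect_error(phantom_config(stratum_fractions = c(0.3, 0.3, 0.4, 0.1, 0.1)),
               "summing to 1")
  expect_error(phantom_config(valley_contrasts = c(S4 = 1.2, S2 = 1.1)),
               "exceed")
  expect_error(phantom_config(s5_contrast_coeffs = c(1, 0, 0.1)), "c2 < 0")
  expect_error(phantom_config(ipl_peak_thickness_um = -4), "positive")
})
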