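test_that("degree-14 polynomials are recovered exactly with R^2 = 1", {
  set.seed(41)
  v <- random_poly14()
  fit <- fit_profile(v)
  expect_equal(fit$fitted, v, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # constant profiles are degenerate with R^2 = 1 by convention
  cfit <- fit_profile(rep(1, 101))
  expect_true(cfit$degenerate)
  expect_equal(cfit$r_squared, 1)
  expect_error(fit_profile(rep(1, 101), excluded = TRUE), "excluded")
  expect_error(fit_profile(rep(1, 50)), "101")
})

test_that("fit R^2 decreases with the noise level on the profile", {
  cfg <- phantom_config()
  base <- true_profile_at(cfg, 2)
  sds <- c(0.01, 0.03, 0.1, 0.3)
  r2 <- vapply(sds, function(s) {
    mean(vapply(1:10, function(i) {
      set.seed(1000 + i)
      fit_profile(base + rnorm(101, 0, s))$r_squared
    }, numeric(1)))
  }, numeric(1))
  expect_lt(stats::cor(sds, r2, method = "spearman"), 0)
  expect_true(all(diff(r2) < 0))
})

test_that("extrema detection accepts the pentalaminar template", {
  cfg <- phantom_config()
  v <- true_profile_at(cfg, 2)
  ex <- find_extrema(fit_profile(v))
  expect_true(ex$valid)
  expect_lt(max(abs(ex$locations - c(9, 26.5, 47, 70.5, 91))), 2)
  expect_true(all(diff(ex$locations) > 0))
  expect_true(all(ex$values[c(1, 3, 5)] > max(ex$values[c(2, 4)])))
})

test_that("monotone profiles are invalid with a no-pattern reason", {
  v <- 0.5 + seq(0, 1, length.out = 101)
  ex <- find_extrema(fit_profile(v))
  expect_false(ex$valid)
  expect_equal(ex$reason, "no-pattern")
})

test_that("closely spaced extrema are suppressed like the brute-force oracle", {
  # four peaks, two of which are closer than the 25% separation rule
  v <- anchored_profile(c(10, 20, 28, 45, 62, 80, 90),
                        c(1.1, 0.95, 1.18, 0.85, 1.12, 0.9, 1.15),
                        edge = c(0.9, 0.9))
  fit <- fit_profile(v)
  ours <- find_extrema(fit)
  oracle <- oracle_extrema(fit$fitted)
  expect_equal(ours$valid, oracle$valid)
  if (ours$valid) expect_equal(ours$locations, oracle$locations)
})

test_that("constrained finder matches the oracle on random polynomials", {
  set.seed(42)
  for (i in 1:100) {
    fit <- fit_profile(random_poly14())
    ours <- find_extrema(fit)
    oracle <- oracle_extrema(fit$fitted)
    expect_identical(ours$valid, oracle$valid)
    if (ours$valid) {
      expect_equal(ours$locations, oracle$locations)
      expect_equal(ours$values, oracle$values)
    }
  }
})

test_that("midpoint boundaries: symmetric pairs cross at the geometric midpoint", {
  # triangular peak at 20, valley at 60, symmetric slopes
  x <- seq(0, 100)
  v <- ifelse(x <= 20, 1.2 - (20 - x) * 0.01,
              ifelse(x <= 60, 1.2 - (x - 20) * 0.01, 0.8 + (x - 60) * 0.01))
  fit <- structure(list(fitted = v, r_squared = 1, degenerate = FALSE),
                   class = "fitted_profile")
  # first crossing of the midpoint value scanning from the peak outward
  mid <- (1.2 + 0.8) / 2
  cross <- which(x > 20 & v <= mid)[1]
  expect_equal(x[cross], 40)
})

test_that("midpoint stratification yields 6 boundaries and 5 thicknesses summing to 100", {
  cfg <- phantom_config()
  fit <- fit_profile(true_profile_at(cfg, 2))
  ex <- find_extrema(fit)
  st <- stratum_boundaries_midpoint(fit, ex)
  expect_true(st$valid)
  expect_length(st$boundaries, 6)
  expect_length(st$thicknesses, 5)
  expect_equal(st$boundaries[1], 0)
  expect_equal(st$boundaries[6], 100)
  expect_true(all(diff(st$boundaries) > 0))
  expect_lt(abs(sum(st$thicknesses) - 100), 1e-6)
  # generator default fractions recovered within 2% IPL (noise-free)
  expect_lt(max(abs(st$thicknesses - cfg$stratum_fractions * 100)), 2)
  # invalid extrema refuse
  bad <- stratum_boundaries_midpoint(fit, list(valid = FALSE))
  expect_false(bad$valid)
})

test_that("transition widths are labeled extrema distances", {
  ex <- list(valid = TRUE, locations = c(10, 30, 50, 70, 90),
             values = c(1.1, 0.9, 1.1, 0.9, 1.1))
  tw <- transition_widths(ex)
  expect_equal(unname(tw), rep(20, 4))
  expect_named(tw, c("S4-S5", "S3-S4", "S2-S3", "S1-S2"))
  # a broad S3 peak 25 and 22 points from its flanking valleys
  ex2 <- list(valid = TRUE, locations = c(8, 22, 47, 69, 90),
              values = c(1.1, 0.9, 1.12, 0.9, 1.1))
  tw2 <- transition_widths(ex2)
  expect_equal(unname(tw2[["S3-S4"]]), 25)
  expect_equal(unname(tw2[["S2-S3"]]), 22)
})

test_that("template-guided search reproduces and constrains segment extrema", {
  cfg <- phantom_config()
  v <- true_profile_at(cfg, 2)
  fit <- fit_profile(v)
  template <- find_extrema(fit)
  # a segment identical to the template gives identical extrema, all valid
  same <- segmental_extrema_with_template(fit, template)
  expect_true(all(same$valid))
  expect_equal(same$locations, template$locations, tolerance = 1)
  # an S5 peak pushed outside the template window is discarded at the edge
  shifted <- anchored_profile(c(35, 50, 60, 75, 91),
                              c(1.2, 0.88, 1.12, 0.9, 1.1))
  sfit <- fit_profile(shifted)
  res <- segmental_extrema_with_template(sfit, template)
  expect_false(res$valid[1])
  expect_equal(res$reasons[1], "edge")
  expect_true(any(res$valid))
  expect_error(segmental_extrema_with_template(fit, list(valid = FALSE)),
               "template")
})

test_that("the 14-parameter vector carries values and missingness correctly", {
  cfg <- phantom_config()
  fit <- fit_profile(true_profile_at(cfg, 2))
  ex <- find_extrema(fit)
  st <- stratum_boundaries_midpoint(fit, ex)
  p <- parameters_per_profile(list(valid = rep(TRUE, 5),
                                   locations = ex$locations,
                                   values = ex$values), st)
  expect_length(p, 14)
  expect_true(all(is.finite(p)))
  expect_lt(abs(sum(p[6:10]) - 100), 1e-6)
  p_none <- parameters_per_profile(list(valid = rep(FALSE, 5),
                                        locations = rep(NA_real_, 5),
                                        values = rep(NA_real_, 5)), NULL)
  expect_true(all(is.na(p_none)))
  # partially valid extrema invalidate only the adjacent transitions
  pv <- parameters_per_profile(list(valid = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                                    locations = c(NA, 26, 47, 70, 91),
                                    values = c(NA, 0.9, 1.1, 0.9, 1.1)), NULL)
  expect_true(is.na(pv[["tr_S4S5"]]))
  expect_false(is.na(pv[["tr_S3S4"]]))
})

test_that("stratification is scale invariant in locations and widths", {
  cfg <- phantom_config()
  v <- true_profile_at(cfg, 2)
  f1 <- fit_profile(v)
  f2 <- fit_profile(v * 4.2)
  e1 <- find_extrema(f1)
  e2 <- find_extrema(f2)
  expect_equal(e1$locations, e2$locations)
  expect_equal(e2$values, e1$values * 4.2, tolerance = 1e-9)
  s1 <- stratum_boundaries_midpoint(f1, e1)
  s2 <- stratum_boundaries_midpoint(f2, e2)
  expect_equal(s1$thicknesses, s2$thicknesses, tolerance = 1e-9)
})
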