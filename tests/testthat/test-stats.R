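test_that("fixed-effects per-subject coefficients equal independent OLS fits", {
  set.seed(61)
  tab <- sim_subject_table(n_subjects = 6, n_segments = 20, slope = 0.05,
                           tau = 0.02)
  spec <- ipl_model_spec("tr_S4S5", "eccentricity_mm")
  fit <- fit_fixed_effects(tab, spec)
  for (s in unique(tab$subject_id)) {
    ols <- stats::coef(stats::lm(tr_S4S5 ~ eccentricity_mm,
                                 tab[tab$subject_id == s, ]))
    row <- fit$per_subject[fit$per_subject$subject == s, ]
    expect_equal(row$intercept, unname(ols[1]), tolerance = 1e-8)
    expect_equal(row$slope, unname(ols[2]), tolerance = 1e-8)
  }
  # single subject: mean slope is that subject's OLS slope
  one <- tab[tab$subject_id == "S01", ]
  f1 <- fit_fixed_effects(one, spec)
  expect_equal(f1$slope,
               unname(stats::coef(stats::lm(tr_S4S5 ~ eccentricity_mm,
                                            one))[2]), tolerance = 1e-8)
})

test_that("slope inference detects real trends and respects their sign", {
  set.seed(62)
  tab <- sim_subject_table(slope = 0.05, tau = 0.01)
  spec <- ipl_model_spec("tr_S4S5", "eccentricity_mm")
  ff <- fit_fixed_effects(tab, spec)
  fm <- fit_mixed_effects(tab, spec)
  expect_lt(ff$p_value, 0.01)
  expect_lt(fm$p_value, 0.01)
  expect_lt(abs(ff$slope - 0.05), 0.01)
  expect_lt(abs(fm$slope - 0.05), 0.01)
  expect_equal(sign(ff$slope), sign(fm$slope))
  expect_true(fm$converged)
})

test_that("mixed fixed slope shrinks between pooled OLS and mean subject slope", {
  # balanced design: every subject measured on the same eccentricity grid
  set.seed(63)
  x <- seq(0.5, 3.75, length.out = 40)
  tab <- do.call(rbind, lapply(1:16, function(s) {
    b <- 0.05 + rnorm(1, 0, 0.04)
    data.frame(subject_id = sprintf("S%02d", s), eccentricity_mm = x,
               ipl_thickness_um = 40,
               tr_S4S5 = 1 + b * x + rnorm(40, 0, 0.08))
  }))
  spec <- ipl_model_spec("tr_S4S5", "eccentricity_mm")
  ff <- fit_fixed_effects(tab, spec)
  fm <- fit_mixed_effects(tab, spec)
  pooled <- unname(stats::coef(stats::lm(tr_S4S5 ~ eccentricity_mm,
                                         tab))[2])
  lo <- min(pooled, ff$slope) - 1e-4
  hi <- max(pooled, ff$slope) + 1e-4
  expect_gte(fm$slope, lo)
  expect_lte(fm$slope, hi)
})

test_that("degenerate between-subject variance matches pooled OLS", {
  set.seed(64)
  tab <- sim_subject_table(slope = 0.03, tau = 0, sigma = 0.05)
  spec <- ipl_model_spec("tr_S4S5", "eccentricity_mm")
  fm <- suppressWarnings(fit_mixed_effects(tab, spec))
  pooled <- unname(stats::coef(stats::lm(tr_S4S5 ~ I(abs(eccentricity_mm)),
                                         tab))[2])
  expect_equal(fm$slope, pooled, tolerance = 0.005)
})

test_that("outlier exclusion removes exactly the injected point", {
  set.seed(65)
  tab <- sim_subject_table(slope = 0.05, sigma = 0.05)
  spec <- ipl_model_spec("tr_S4S5", "eccentricity_mm")
  clean <- exclude_outliers(tab, spec)
  expect_equal(attr(clean, "n_removed_outlier"), 0)
  expect_equal(nrow(clean), nrow(tab))
  tab2 <- tab
  tab2$tr_S4S5[100] <- tab2$tr_S4S5[100] + 10 * 0.05 * 2
  out <- exclude_outliers(tab2, spec)
  expect_equal(attr(out, "n_removed_outlier"), 1)
  expect_false(100 %in% as.integer(rownames(out)))
  # sub-threshold thickness rows are dropped first
  tab3 <- tab
  tab3$ipl_thickness_um[1:10] <- 20
  out3 <- exclude_outliers(tab3, spec)
  expect_equal(attr(out3, "n_removed_thickness"), 10)
})

test_that("quadratic fits recover the S5 vertex", {
  set.seed(66)
  spec <- ipl_model_spec("S5", "eccentricity_mm")
  expect_equal(spec$degree, 2L)
  # exact parabola: vertex recovered exactly
  tab <- sim_subject_table(n_subjects = 4, n_segments = 30, sigma = 0)
  tab$S5 <- 1.2 - 0.055 * (tab$eccentricity_mm - 2.4)^2
  fit <- fit_fixed_effects(tab, spec)
  vx <- vertex_eccentricity(fit)
  expect_true(all(vx$valid))
  expect_equal(vx$vertex_mm, rep(2.4, 4), tolerance = 1e-6)
  # invariant to adding a constant to the dependent variable
  tab$S5 <- tab$S5 + 5
  vx2 <- vertex_eccentricity(fit_fixed_effects(tab, spec))
  expect_equal(vx2$vertex_mm, vx$vertex_mm, tolerance = 1e-6)
  # positive quadratic coefficient flagged, no vertex
  tab$S5 <- 1 + 0.05 * (tab$eccentricity_mm - 2)^2
  vx3 <- vertex_eccentricity(fit_fixed_effects(tab, spec))
  expect_true(all(!vx3$valid))
  expect_true(all(is.na(vx3$vertex_mm)))
  expect_error(vertex_eccentricity(
    fit_fixed_effects(tab, ipl_model_spec("S5", "eccentricity_mm",
                                          degree = 1))), "quadratic")
})

test_that("strata ANOVA with Tukey HSD separates shifted groups only", {
  set.seed(67)
  n <- 200
  base <- rnorm(n, 20, 1)
  # literally identical groups: every pairwise difference is exactly zero
  tab <- data.frame(th_S5 = base, th_S4 = base, th_S3 = base,
                    th_S2 = base, th_S1 = base)
  an <- compare_strata_anova(tab, "thickness")
  expect_true(all(an$pairs$p_adj > 0.99))
  expect_true(all(an$pairs$diff == 0))
  tab$th_S3 <- rnorm(n, 25, 1)    # one group shifted by 5 SD
  an2 <- compare_strata_anova(tab, "thickness")
  s3_pairs <- grepl("th_S3", an2$pairs$pair)
  expect_true(all(an2$pairs$p_adj[s3_pairs] < 0.05))
  expect_error(compare_strata_anova(tab[, "th_S3", drop = FALSE]),
               "undefined columns|groups")
})

test_that("AIC comparison prefers the true model structure", {
  set.seed(68)
  spec1 <- ipl_model_spec("S5", "eccentricity_mm", degree = 1)
  spec2 <- ipl_model_spec("S5", "eccentricity_mm", degree = 2)
  tab <- sim_subject_table(n_subjects = 8, slope = 0.02, sigma = 0.05)
  tab$S5 <- 1.2 - 0.08 * (tab$eccentricity_mm - 2.4)^2 +
    rnorm(nrow(tab), 0, 0.03)
  f1 <- fit_fixed_effects(tab, spec1)
  f2 <- fit_fixed_effects(tab, spec2)
  cmp <- compare_models_aic(list(linear = f1, quadratic = f2))
  expect_equal(cmp$model[1], "quadratic")
  expect_equal(min(cmp$delta_aic), 0)
  # identical models tie at delta 0
  cmp2 <- compare_models_aic(list(a = f1, b = f1))
  expect_true(all(cmp2$delta_aic == 0))
  # mismatched rows refuse
  f3 <- fit_fixed_effects(tab[-(1:5), ], spec1)
  expect_error(compare_models_aic(list(a = f1, b = f3)), "different rows")
})

test_that("residual diagnostics flag heteroscedasticity and degeneracy", {
  set.seed(69)
  spec <- ipl_model_spec("tr_S4S5", "eccentricity_mm")
  # variance proportional to predictor^2: flag raised
  tab <- sim_subject_table(slope = 0.3, sigma = 0)
  tab$tr_S4S5 <- tab$tr_S4S5 +
    rnorm(nrow(tab), 0, 0.2 * tab$eccentricity_mm^2)
  d <- residual_diagnostics(fit_fixed_effects(tab, spec))
  expect_true(d$heteroscedastic)
  expect_false(d$degenerate)
  expect_false(is.null(d$conf_int))
  # perfect fit: degenerate, flagged rather than tested
  tab2 <- sim_subject_table(slope = 0.05, sigma = 0)
  d2 <- residual_diagnostics(fit_fixed_effects(tab2, spec))
  expect_true(d2$degenerate)
})

test_that("the model battery enumerates 56 models", {
  set.seed(70)
  tab <- sim_subject_table(n_subjects = 6, n_segments = 15, slope = 0.02,
                           tau = 0.005)
  # populate all 14 parameters with noisy copies
  for (p in setdiff(iplstrat:::parameter_names(), c("S5", "tr_S4S5")))
    tab[[p]] <- tab$S5 + rnorm(nrow(tab), 0, 0.05)
  models <- fit_all_models(tab, min_rows = 30)
  expect_equal(nrow(models), 56)
  expect_equal(sum(models$model_type == "mixed"), 28)
  expect_equal(unique(models$degree[models$parameter == "S5" &
                                      models$predictor == "eccentricity_mm"]),
               2L)
  expect_true(all(models$degree[models$parameter != "S5"] == 1L))
})
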