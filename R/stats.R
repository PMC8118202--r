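#' Specification of a subject-level model
#'
#' Describes one model of a stratification parameter against eccentricity
#' magnitude or IPL thickness: polynomial degree and whether per-subject
#' coefficients are free (fixed-effects) or zero-mean normal random
#' deviations around population coefficients (mixed-effects). By default
#' only the S5 peak versus eccentricity uses a quadratic term; all other
#' parameter/predictor combinations are linear.
#'
#' @param dependent One of the 14 parameter names ([parameters_per_profile()]).
#' @param predictor `"eccentricity_mm"` (magnitude is used) or
#'   `"ipl_thickness_um"`.
#' @param degree 1 (linear) or 2 (quadratic); `NULL` selects 2 for
#'   S5 versus eccentricity and 1 otherwise.
#' @param random_effects Logical: mixed (TRUE) or fixed (FALSE) effects.
#' @return An object of class `ipl_model_spec`.
#' @export
ipl_model_spec <- function(dependent,
                           predictor = c("eccentricity_mm",
                                         "ipl_thickness_um"),
                           degree = NULL, random_effects = FALSE) {
  predictor <- match.arg(predictor)
  stopifnot(dependent %in% parameter_names())
  if (is.null(degree))
    degree <- if (dependent == "S5" && predictor == "eccentricity_mm") 2L else 1L
  stopifnot(degree %in% 1:2)
  structure(list(dependent = dependent, predictor = predictor,
                 degree = as.integer(degree),
                 random_effects = isTRUE(random_effects)),
            class = "ipl_model_spec")
}

# Model frame: subject, x (predictor; |e| for eccentricity), y. NA rows
# dropped; row ids retained for AIC comparability checks.
model_frame <- function(table, spec) {
  x <- table[[spec$predictor]]
  if (spec$predictor == "eccentricity_mm") x <- abs(x)
  y <- table[[spec$dependent]]
  ok <- !is.na(x) & !is.na(y) & !is.na(table$subject_id)
  data.frame(subject = factor(table$subject_id[ok]), x = x[ok], y = y[ok],
             row_id = which(ok))
}

#' Exclude sub-threshold and outlying segments
#'
#' Removes rows whose IPL thickness is below the analysis threshold, then
#' (single pass) rows whose residual from an initial per-subject polynomial
#' fit exceeds `sd_limit` standard deviations of the residuals.
#'
#' @param table A cohort table.
#' @param spec An [ipl_model_spec()] defining dependent/predictor/degree for
#'   the residual screen.
#' @param sd_limit Residual exclusion threshold in residual SDs.
#' @param thickness_min_um IPL thickness threshold (um); rows below it are
#'   dropped when the table has an `ipl_thickness_um` column.
#' @return The filtered table, with attributes `n_removed_thickness` and
#'   `n_removed_outlier`.
#' @export
exclude_outliers <- function(table, spec, sd_limit = 5,
                             thickness_min_um = 24) {
  stopifnot(inherits(spec, "ipl_model_spec"))
  n0 <- nrow(table)
  if ("ipl_thickness_um" %in% names(table))
    table <- table[is.na(table$ipl_thickness_um) |
                     table$ipl_thickness_um >= thickness_min_um, ,
                   drop = FALSE]
  n_thick <- n0 - nrow(table)
  mf <- model_frame(table, spec)
  drop_rows <- integer(0)
  if (nrow(mf) > 3 * nlevels(mf$subject)) {
    fit <- tryCatch(suppressWarnings(fit_fixed_effects(table, spec)),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      res <- stats::residuals(fit$model)
      s <- stats::sd(res)
      if (is.finite(s) && s > 0) {
        bad <- abs(res) > sd_limit * s
        drop_rows <- fit$data$row_id[bad]
      }
    }
  }
  out <- if (length(drop_rows)) table[-drop_rows, , drop = FALSE] else table
  attr(out, "n_removed_thickness") <- n_thick
  attr(out, "n_removed_outlier") <- length(drop_rows)
  out
}

# Map centered-polynomial coefficients (a, b1, b2 at x - m) back to
# original-unit intercept/slope/quadratic.
uncenter_coefs <- function(a, b1, b2, m) {
  b2 <- ifelse(is.na(b2), 0, b2)
  data.frame(intercept = a - b1 * m + b2 * m^2,
             slope = b1 - 2 * b2 * m,
             quad = b2)
}

#' Fixed-effects model: free per-subject coefficients
#'
#' Fits every subject's own intercept, slope (and quadratic term for degree
#' 2) by ordinary least squares in a single linear model with
#' subject-by-predictor interactions (one shared residual variance; the
#' per-subject coefficients equal independent per-subject OLS fits).
#' Group-level inference on the slope is a two-tailed t-test of the subject
#' slopes against zero; the reported slope is the mean of the subject
#' slopes. The predictor is centered before fitting to reduce collinearity
#' with the quadratic term; reported coefficients are in original units.
#'
#' @param table A cohort table (or any data frame with `subject_id`, the
#'   predictor and the dependent columns).
#' @param spec An [ipl_model_spec()].
#' @param min_segments Minimum observations per subject; subjects with
#'   fewer (or with a singular design) are dropped with a warning.
#' @return An `ipl_model_fit` list: `type = "fixed"`, `per_subject`
#'   coefficients (original units), `slope` (mean subject slope), `p_value`
#'   (t-test of subject slopes vs 0), `t`, `df`, `aic`, `model` (the `lm`),
#'   `data` (model frame), `spec`, `center`.
#' @export
fit_fixed_effects <- function(table, spec, min_segments = 3) {
  stopifnot(inherits(spec, "ipl_model_spec"))
  mf <- model_frame(table, spec)
  counts <- table(mf$subject)
  ok_subj <- names(counts)[counts >= max(min_segments, spec$degree + 1)]
  if (length(ok_subj) < length(counts))
    warning(length(counts) - length(ok_subj),
            " subject(s) dropped: too few segments for the design")
  mf <- droplevels(mf[mf$subject %in% ok_subj, , drop = FALSE])
  if (!nlevels(mf$subject))
    stop("no subject has enough segments to fit", call. = FALSE)
  m <- mean(mf$x)
  mf$xc <- mf$x - m
  mf$xc2 <- mf$xc^2
  subj <- levels(mf$subject)
  one_subject <- length(subj) == 1
  fml <- if (one_subject) {
    if (spec$degree == 2) y ~ xc + xc2 else y ~ xc
  } else if (spec$degree == 2) {
    y ~ 0 + subject + subject:xc + subject:xc2
  } else y ~ 0 + subject + subject:xc
  fit <- stats::lm(fml, data = mf)
  cf <- stats::coef(fit)
  if (one_subject) {
    a <- cf[["(Intercept)"]]
    b1 <- cf[["xc"]]
    b2 <- if (spec$degree == 2) cf[["xc2"]] else NA_real_
  } else {
    a <- cf[paste0("subject", subj)]
    b1 <- cf[paste0("subject", subj, ":xc")]
    b2 <- if (spec$degree == 2) cf[paste0("subject", subj, ":xc2")] else
      rep(NA_real_, length(subj))
  }
  if (anyNA(a) || anyNA(b1) || (spec$degree == 2 && anyNA(b2))) {
    bad <- is.na(a) | is.na(b1) | (spec$degree == 2 & is.na(b2))
    warning(sum(bad), " subject(s) dropped: singular design")
    keep <- subj[!bad]
    return(fit_fixed_effects(table[table$subject_id %in% keep, , drop = FALSE],
                             spec, min_segments))
  }
  per_subject <- cbind(data.frame(subject = subj),
                       uncenter_coefs(a, b1, b2, m))
  # group-level t-test of the subject slopes against zero; undefined with a
  # single subject or (numerically) identical slopes
  tt <- if (length(subj) >= 2)
    tryCatch(stats::t.test(per_subject$slope), error = function(e) NULL)
  else NULL
  structure(list(type = "fixed", spec = spec, per_subject = per_subject,
                 slope = mean(per_subject$slope),
                 p_value = if (is.null(tt)) NA_real_ else tt$p.value,
                 t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
                 df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
                 aic = stats::AIC(fit), model = fit, data = mf,
                 center = m, converged = TRUE),
            class = "ipl_model_fit")
}

#' Mixed-effects model: random per-subject deviations
#'
#' Fits a linear mixed model with population (fixed) intercept, slope and,
#' for degree 2, quadratic term, plus independent zero-mean normal random
#' intercept/slope(/quadratic) per subject (diagonal random-effects
#' covariance). Estimated by REML via \pkg{lme4}. p-values for the fixed
#' coefficients are normal-approximation Wald tests. If the fit fails to
#' converge the random structure is simplified to a random intercept and
#' the result flagged. The predictor is centered internally; reported
#' coefficients are in original units.
#'
#' @param table A cohort table.
#' @param spec An [ipl_model_spec()].
#' @return An `ipl_model_fit` list: `type = "mixed"`, `slope` (fixed slope,
#'   original units), `p_value` (Wald), `fixed` (intercept/slope/quad),
#'   `per_subject` (fixed + BLUP deviations), `aic` (REML), `model` (the
#'   `lmerMod`), `converged`, `data`, `spec`, `center`.
#' @export
fit_mixed_effects <- function(table, spec) {
  stopifnot(inherits(spec, "ipl_model_spec"))
  mf <- model_frame(table, spec)
  if (nlevels(mf$subject) < 2)
    stop("mixed model requires at least 2 subjects", call. = FALSE)
  m <- mean(mf$x)
  mf$xc <- mf$x - m
  mf$xc2 <- mf$xc^2
  fml <- if (spec$degree == 2)
    y ~ xc + xc2 + (1 | subject) + (0 + xc | subject) + (0 + xc2 | subject)
  else
    y ~ xc + (1 | subject) + (0 + xc | subject)
  fit <- NULL
  converged <- TRUE
  withCallingHandlers(
    fit <- lme4::lmer(fml, data = mf, REML = TRUE),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (!converged) {
    warning("mixed model did not converge cleanly; ",
            "falling back to a random-intercept model")
    fml2 <- if (spec$degree == 2) y ~ xc + xc2 + (1 | subject) else
      y ~ xc + (1 | subject)
    fit <- suppressWarnings(lme4::lmer(fml2, data = mf, REML = TRUE))
  }
  sm <- summary(fit)$coefficients
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  p_wald <- 2 * stats::pnorm(-abs(est / se))
  a <- est[["(Intercept)"]]
  b1 <- est[["xc"]]
  b2 <- if (spec$degree == 2) est[["xc2"]] else NA_real_
  fixed <- uncenter_coefs(a, b1, b2, m)
  re <- lme4::ranef(fit)$subject
  subj <- rownames(re)
  ra <- a + re[["(Intercept)"]]
  rb1 <- b1 + (if ("xc" %in% names(re)) re[["xc"]] else 0)
  rb2 <- if (spec$degree == 2)
    b2 + (if ("xc2" %in% names(re)) re[["xc2"]] else 0) else
      rep(NA_real_, length(subj))
  per_subject <- cbind(data.frame(subject = subj),
                       uncenter_coefs(ra, rb1, rb2, m))
  structure(list(type = "mixed", spec = spec, fixed = fixed,
                 per_subject = per_subject,
                 slope = fixed$slope,
                 p_value = unname(p_wald[["xc"]]),
                 wald_p = p_wald, std_errors = se,
                 aic = stats::AIC(fit), model = fit, data = mf,
                 center = m, converged = converged),
            class = "ipl_model_fit")
}

#' Per-subject vertex eccentricity of a quadratic fit
#'
#' For a degree-2 model of a parameter against eccentricity, computes each
#' subject's vertex (the eccentricity maximizing the fitted parabola),
#' `-b / (2c)` in original units. Subjects with a non-negative quadratic
#' coefficient have no maximum and are flagged invalid. The estimator is
#' invariant to adding a constant to the dependent variable.
#'
#' @param fit An `ipl_model_fit` from a degree-2 spec.
#' @return Data frame: `subject`, `vertex_mm`, `valid`.
#' @export
vertex_eccentricity <- function(fit) {
  stopifnot(inherits(fit, "ipl_model_fit"))
  if (fit$spec$degree != 2)
    stop("vertex requires a quadratic (degree 2) model", call. = FALSE)
  ps <- fit$per_subject
  valid <- is.finite(ps$quad) & ps$quad < 0
  data.frame(subject = ps$subject,
             vertex_mm = ifelse(valid, -ps$slope / (2 * ps$quad), NA_real_),
             valid = valid)
}

#' ANOVA with Tukey HSD across strata
#'
#' One-way analysis of variance across the five strata of one parameter
#' family (extrema contrasts, stratum thicknesses, or transition widths),
#' followed by Tukey's Honest Significant Difference test for adjusted
#' pairwise comparisons.
#'
#' @param table A cohort table.
#' @param family `"thickness"`, `"extrema"` or `"transition"`.
#' @return A list: `anova_p`, `pairs` (data frame of pairwise differences
#'   with Tukey-adjusted p-values), `group_means`.
#' @export
compare_strata_anova <- function(table,
                                 family = c("thickness", "extrema",
                                            "transition")) {
  family <- match.arg(family)
  cols <- switch(family,
                 thickness = paste0("th_", c("S5", "S4", "S3", "S2", "S1")),
                 extrema = c("S5", "S4", "S3", "S2", "S1"),
                 transition = c("tr_S4S5", "tr_S3S4", "tr_S2S3", "tr_S1S2"))
  cols <- intersect(cols, names(table))
  if (length(cols) < 2)
    stop("need at least 2 strata groups with data", call. = FALSE)
  long <- do.call(rbind, lapply(cols, function(cn)
    data.frame(group = cn, value = table[[cn]])))
  long <- long[!is.na(long$value), , drop = FALSE]
  long$group <- factor(long$group, levels = cols)
  if (length(unique(long$group)) < 2)
    stop("need at least 2 strata groups with data", call. = FALSE)
  av <- stats::aov(value ~ group, data = long)
  tk <- stats::TukeyHSD(av)$group
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova_p = summary(av)[[1]][["Pr(>F)"]][1],
       pairs = pairs,
       group_means = tapply(long$value, long$group, mean))
}

#' Compare competing models by AIC
#'
#' Models must be fitted on identical rows. Mixed models estimated by REML
#' are refitted by maximum likelihood so that models with different fixed
#' structures are comparable; plain linear models use their ML AIC.
#'
#' @param fits Named list of `ipl_model_fit` objects.
#' @return Data frame with `model`, `aic`, `delta_aic` (vs the minimum),
#'   sorted ascending; lower is preferred.
#' @export
compare_models_aic <- function(fits) {
  stopifnot(length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "ipl_model_fit")))
  rows <- lapply(fits, function(f) sort(f$data$row_id))
  if (!all(vapply(rows, identical, logical(1), rows[[1]])))
    stop("models were fitted on different rows; AIC not comparable",
         call. = FALSE)
  aic <- vapply(fits, function(f) {
    if (f$type == "mixed") stats::AIC(lme4::refitML(f$model))
    else stats::AIC(f$model)
  }, numeric(1))
  out <- data.frame(model = names(fits) %||% seq_along(fits), aic = aic,
                    delta_aic = aic - min(aic), row.names = NULL)
  out[order(out$aic), , drop = FALSE]
}

#' Residual diagnostics: homoscedasticity and confidence intervals
#'
#' A Breusch-Pagan-type screen (squared residuals regressed on fitted
#' values; LM statistic n R^2 against chi-squared with 1 df) plus Wald
#' confidence intervals for all estimated coefficients. Degenerate fits
#' (zero residual variance) are flagged rather than tested.
#'
#' @param fit An `ipl_model_fit`.
#' @param alpha Flagging level for the heteroscedasticity test.
#' @return A list: `bp_stat`, `bp_p`, `heteroscedastic`, `degenerate`,
#'   `conf_int` (matrix of 95% intervals).
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "ipl_model_fit"))
  res <- stats::residuals(fit$model)
  ftd <- stats::fitted(fit$model)
  n <- length(res)
  if (stats::var(res) < 1e-24)
    return(list(bp_stat = NA_real_, bp_p = NA_real_,
                heteroscedastic = FALSE, degenerate = TRUE,
                conf_int = NULL))
  aux <- stats::lm(I(res^2) ~ ftd)
  r2 <- summary(aux)$r.squared
  stat <- n * r2
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  ci <- if (fit$type == "mixed") {
    est <- lme4::fixef(fit$model)
    se <- fit$std_errors[names(est)]
    cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)
  } else {
    suppressMessages(stats::confint(fit$model))
  }
  list(bp_stat = unname(stat), bp_p = unname(p),
       heteroscedastic = p < alpha, degenerate = FALSE, conf_int = ci)
}

#' Fit the full battery of subject-level models
#'
#' Enumerates every combination of the 14 stratification parameters and the
#' two predictors (eccentricity magnitude, IPL thickness), each as a fixed-
#' and a mixed-effects model (56 models in total); the S5-versus-
#' eccentricity data set automatically receives a quadratic term. Rows are
#' screened with [exclude_outliers()] per model.
#'
#' @param table A cohort table.
#' @param min_rows Skip combinations with fewer valid rows.
#' @return Data frame with one row per model: `parameter`, `predictor`,
#'   `model_type`, `degree`, `slope`, `p_value`, `aic`, `n`, `converged`
#'   (NA rows for combinations that could not be fitted).
#' @export
fit_all_models <- function(table, min_rows = 30) {
  out <- list()
  for (param in parameter_names()) {
    for (pred in c("eccentricity_mm", "ipl_thickness_um")) {
      for (mixed in c(FALSE, TRUE)) {
        spec <- ipl_model_spec(param, pred, random_effects = mixed)
        row <- data.frame(parameter = param, predictor = pred,
                          model_type = if (mixed) "mixed" else "fixed",
                          degree = spec$degree, slope = NA_real_,
                          p_value = NA_real_, aic = NA_real_, n = NA_integer_,
                          converged = NA)
        tab <- tryCatch(suppressWarnings(exclude_outliers(table, spec)),
                        error = function(e) table)
        mf <- model_frame(tab, spec)
        if (nrow(mf) >= min_rows) {
          f <- tryCatch(suppressMessages(suppressWarnings(
            if (mixed) fit_mixed_effects(tab, spec)
            else fit_fixed_effects(tab, spec))), error = function(e) NULL)
          if (!is.null(f)) {
            row$slope <- f$slope
            row$p_value <- f$p_value
            row$aic <- f$aic
            row$n <- nrow(f$data)
            row$converged <- f$converged
          }
        }
        out[[length(out) + 1]] <- row
      }
    }
  }
  do.call(rbind, out)
}
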