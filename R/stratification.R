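#' Fit a 14th-order polynomial to an IPL profile
#'
#' Least-squares fit of a degree-14 polynomial (orthogonal basis for
#' numerical stability) to the 101 points of a percent-axis IPL profile.
#' The fit suppresses residual speckle and additive-noise fluctuations while
#' retaining the pentalaminar pattern; all downstream feature extraction
#' operates on the fitted curve sampled back on the 101-point grid.
#'
#' @param values Numeric vector of 101 profile values, or a single-row
#'   selection from an `ipl_profiles` object.
#' @param excluded Logical; refuse to fit profiles flagged excluded.
#' @return An object of class `fitted_profile`: `fitted` (101 values),
#'   `r_squared`, and `degenerate` (TRUE when the input had zero variance,
#'   in which case R^2 is defined as 1 by convention).
#' @export
fit_profile <- function(values, excluded = FALSE) {
  if (isTRUE(excluded))
    stop("refusing to fit an excluded profile", call. = FALSE)
  values <- as.numeric(values)
  if (length(values) != 101 || any(!is.finite(values)))
    stop("profile must be 101 finite values", call. = FALSE)
  x <- percent_axis()
  if (stats::var(values) < .Machine$double.eps) {
    return(structure(list(fitted = values, r_squared = 1,
                          degenerate = TRUE), class = "fitted_profile"))
  }
  fit <- stats::lm(values ~ stats::poly(x, 14))
  fitted <- as.numeric(stats::fitted(fit))
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((values - mean(values))^2)
  structure(list(fitted = fitted, r_squared = 1 - ss_res / ss_tot,
                 degenerate = FALSE), class = "fitted_profile")
}

# All local extrema of a vector on the open interior grid (indices 2..n-1),
# by direct neighbor comparison. Returns 0-based grid locations.
grid_extrema <- function(v) {
  i <- 2:(length(v) - 1)
  list(max = i[v[i] > v[i - 1] & v[i] > v[i + 1]] - 1L,
       min = i[v[i] < v[i - 1] & v[i] < v[i + 1]] - 1L)
}

# Greedy minimum-separation suppression, mirroring peak finding with a
# minimum peak distance: candidates are processed in order of decreasing
# prominence (peak height, or valley depth for minima; ties broken by
# location) and kept only if at least `min_sep` grid points from every
# already-kept candidate of the same type.
suppress_close <- function(locs, vals, min_sep, maxima = TRUE) {
  if (!length(locs)) return(integer(0))
  ord <- order(if (maxima) -vals else vals, locs)
  kept <- integer(0)
  for (i in ord) {
    if (all(abs(locs[i] - kept) >= min_sep)) kept <- c(kept, locs[i])
  }
  sort(kept)
}

#' Detect the five IPL extrema on a fitted profile
#'
#' Finds local maxima and minima of the fitted polynomial evaluated on the
#' 101-point grid (endpoints excluded), enforces that consecutive maxima and
#' consecutive minima are separated by more than 25% of the IPL thickness
#' (lower-prominence extrema are suppressed), and accepts the result only if
#' the surviving extrema form the peak-valley-peak-valley-peak template
#' (S5, S4, S3, S2, S1 from 0% to 100%). Otherwise the result is invalid
#' with a machine-readable reason.
#'
#' @param fit A `fitted_profile`.
#' @param min_separation Minimum separation between same-type extrema in
#'   grid points; 26 encodes "greater than 25% of the IPL thickness".
#' @return A list: `valid`, `locations` (5, % IPL), `values` (5), `reason`.
#' @export
find_extrema <- function(fit, min_separation = 26) {
  stopifnot(inherits(fit, "fitted_profile"))
  v <- fit$fitted
  ge <- grid_extrema(v)
  # minima lying outside the outermost maxima belong to the descent into
  # the bordering GCL / INL troughs (or to edge ringing of the polynomial
  # fit), not to an IPL stratum: the template starts and ends with a peak,
  # so only valleys between peaks are candidates
  if (length(ge$max))
    ge$min <- ge$min[ge$min > min(ge$max) & ge$min < max(ge$max)]
  mx <- suppress_close(ge$max, v[ge$max + 1L], min_separation, maxima = TRUE)
  mn <- suppress_close(ge$min, v[ge$min + 1L], min_separation, maxima = FALSE)
  invalid <- function(reason)
    list(valid = FALSE, locations = rep(NA_real_, 5),
         values = rep(NA_real_, 5), reason = reason)
  if (length(mx) == 0 && length(mn) == 0) return(invalid("no-pattern"))
  if (length(mx) != 3 || length(mn) != 2) return(invalid("no-pattern"))
  locs <- sort(c(mx, mn))
  types <- ifelse(locs %in% mx, "max", "min")
  if (!identical(types, c("max", "min", "max", "min", "max")))
    return(invalid("no-pattern"))
  list(valid = TRUE, locations = as.numeric(locs), values = v[locs + 1L],
       reason = "")
}

#' Stratum boundaries by the midpoint-crossing rule
#'
#' For each adjacent peak-valley pair, the stratum boundary is the first
#' position (scanning from the inner extremum toward the outer) where the
#' fitted profile crosses the value midway between the two extrema. With
#' the inner IPL boundary at 0% and the outer at 100%, the four crossings
#' yield 6 boundaries delineating the 5 strata; thicknesses are the
#' successive differences and sum to 100 by construction.
#'
#' @param fit A `fitted_profile`.
#' @param extrema Output of [find_extrema()] (must be valid).
#' @return A list: `valid`, `boundaries` (6, % IPL), `thicknesses` (named
#'   S5..S1, % IPL), `reason`.
#' @export
stratum_boundaries_midpoint <- function(fit, extrema) {
  stopifnot(inherits(fit, "fitted_profile"))
  if (!isTRUE(extrema$valid))
    return(list(valid = FALSE, boundaries = rep(NA_real_, 6),
                thicknesses = rep(NA_real_, 5), reason = "invalid-extrema"))
  v <- fit$fitted
  crossings <- numeric(4)
  for (k in 1:4) {
    mid <- (extrema$values[k] + extrema$values[k + 1]) / 2
    i0 <- extrema$locations[k]
    i1 <- extrema$locations[k + 1]
    found <- NA_real_
    for (i in i0:(i1 - 1)) {
      a <- v[i + 1L] - mid          # value at grid point i (0-based)
      b <- v[i + 2L] - mid
      if (a == 0) { found <- i; break }
      if (a * b < 0) { found <- i + a / (a - b); break }
      if (b == 0) { found <- i + 1; break }
    }
    if (is.na(found))
      return(list(valid = FALSE, boundaries = rep(NA_real_, 6),
                  thicknesses = rep(NA_real_, 5), reason = "no-crossing"))
    crossings[k] <- found
  }
  boundaries <- c(0, crossings, 100)
  th <- diff(boundaries)
  names(th) <- c("S5", "S4", "S3", "S2", "S1")
  list(valid = TRUE, boundaries = boundaries, thicknesses = th, reason = "")
}

#' Inter-stratum transition widths
#'
#' Distances (% IPL) between adjacent extrema locations: S4--S5, S3--S4,
#' S2--S3, S1--S2 (inner to outer). These quantify the sharpness of the
#' transitions between strata and provide a consistency check on the
#' midpoint-crossing thicknesses.
#'
#' @param extrema Output of [find_extrema()] or the segmental search.
#' @return Named numeric vector of 4 transition widths (`NA` where either
#'   flanking extremum is invalid).
#' @export
transition_widths <- function(extrema) {
  tw <- diff(extrema$locations)
  names(tw) <- c("S4-S5", "S3-S4", "S2-S3", "S1-S2")
  tw
}

#' Template-guided segmental extrema search
#'
#' Locates the five extrema of a segmental fitted profile using the
#' image-averaged profile's extrema as a template: each extremum is searched
#' only on grid points strictly between the template's previous and next
#' extrema locations (clipped to the open interval (0, 100)). An extremum
#' landing on the edge of its search range is considered invalid, as is any
#' adjacent valid pair violating the peak-above-valley pattern. Validity is
#' recorded per extremum, so a single bad extremum does not discard the
#' rest.
#'
#' @param segment_fit A `fitted_profile` for one segment.
#' @param template_extrema Valid [find_extrema()] result for the
#'   image-average profile.
#' @return A list: `locations` (5), `values` (5), `valid` (logical 5),
#'   `reasons` (character 5).
#' @export
segmental_extrema_with_template <- function(segment_fit, template_extrema) {
  stopifnot(inherits(segment_fit, "fitted_profile"))
  if (!isTRUE(template_extrema$valid))
    stop("template extrema must be valid; discard the image instead",
         call. = FALSE)
  v <- segment_fit$fitted
  tl <- template_extrema$locations
  bounds <- c(0, tl, 100)
  locations <- rep(NA_real_, 5)
  values <- rep(NA_real_, 5)
  valid <- rep(FALSE, 5)
  reasons <- rep("", 5)
  for (k in 1:5) {
    lower <- bounds[k]
    upper <- bounds[k + 2]
    grid <- seq.int(ceiling(lower + 1e-9), floor(upper - 1e-9))
    grid <- grid[grid > lower & grid < upper & grid >= 1 & grid <= 99]
    if (length(grid) < 3) { reasons[k] <- "window"; next }
    vals <- v[grid + 1L]
    idx <- if (k %% 2 == 1) which.max(vals) else which.min(vals)
    locations[k] <- grid[idx]
    values[k] <- vals[idx]
    if (idx == 1 || idx == length(vals)) {
      reasons[k] <- "edge"
    } else {
      valid[k] <- TRUE
    }
  }
  # peak-valley-peak-valley-peak consistency among valid neighbors
  for (k in 1:4) {
    if (valid[k] && valid[k + 1]) {
      peak <- if (k %% 2 == 1) values[k] else values[k + 1]
      valley <- if (k %% 2 == 1) values[k + 1] else values[k]
      if (peak <= valley) {
        valid[c(k, k + 1)] <- FALSE
        reasons[c(k, k + 1)] <- "pattern"
      }
    }
  }
  list(locations = locations, values = values, valid = valid,
       reasons = reasons)
}

# Canonical names of the 14 stratification parameters: extrema contrasts,
# midpoint stratum thicknesses, inter-stratum transition widths.
parameter_names <- function() {
  c("S5", "S4", "S3", "S2", "S1",
    "th_S5", "th_S4", "th_S3", "th_S2", "th_S1",
    "tr_S4S5", "tr_S3S4", "tr_S2S3", "tr_S1S2")
}

#' Assemble the 14 stratification parameters
#'
#' Collects the five extrema contrasts, five midpoint stratum thicknesses
#' and four transition widths of one profile into a named 14-element vector.
#' Invalid slots carry `NA`.
#'
#' @param extrema Extrema result (template-guided or [find_extrema()]).
#' @param strata Midpoint result from [stratum_boundaries_midpoint()], or
#'   `NULL` when unavailable.
#' @return Named numeric vector of length 14.
#' @export
parameters_per_profile <- function(extrema, strata = NULL) {
  out <- rep(NA_real_, 14)
  names(out) <- parameter_names()
  valid <- if (!is.null(extrema$valid) && length(extrema$valid) == 5)
    extrema$valid else rep(isTRUE(extrema$valid), 5)
  out[1:5][valid] <- extrema$values[valid]
  if (!is.null(strata) && isTRUE(strata$valid))
    out[6:10] <- strata$thicknesses
  tw <- transition_widths(extrema)
  tw[!(valid[-5] & valid[-1])] <- NA_real_
  out[11:14] <- tw
  out
}

#' Stratify all segments of one image with its average-profile template
#'
#' The image-average profile (unweighted mean of the non-excluded normalized
#' segment profiles) is fitted and its extrema detected with the separation
#' and pattern rules. If the template fails, all segments of the image are
#' discarded (reason "template"). Otherwise each non-excluded segment is
#' fitted and analysed with the template-guided search; midpoint stratum
#' thicknesses are computed when all five extrema are valid.
#'
#' @param profiles An `ipl_profiles` object for one image.
#' @return A list: `table` (one row per segment: metadata, `r_squared`, the
#'   14 parameters, `discard_reason`), `template` (fit + extrema of the
#'   average profile), `average_profile` (101 values or NULL).
#' @export
stratify_image <- function(profiles) {
  stopifnot(inherits(profiles, "ipl_profiles"))
  meta <- profiles$meta
  n_seg <- nrow(meta)
  params <- matrix(NA_real_, n_seg, 14,
                   dimnames = list(NULL, parameter_names()))
  locs <- matrix(NA_real_, n_seg, 5,
                 dimnames = list(NULL, paste0("loc_",
                                              c("S5", "S4", "S3", "S2", "S1"))))
  r2 <- rep(NA_real_, n_seg)
  reason <- ifelse(meta$excluded, meta$reason, "")
  usable <- !meta$excluded & !is.na(profiles$values[, 1])
  template <- NULL
  avg <- NULL
  if (any(usable)) {
    avg <- colMeans(profiles$values[usable, , drop = FALSE])
    tfit <- fit_profile(avg)
    text <- find_extrema(tfit)
    template <- list(fit = tfit, extrema = text)
    if (!text$valid) {
      reason[usable] <- "template"
    } else {
      for (s in which(usable)) {
        sfit <- fit_profile(profiles$values[s, ])
        r2[s] <- sfit$r_squared
        sext <- segmental_extrema_with_template(sfit, text)
        strata <- if (all(sext$valid)) {
          stratum_boundaries_midpoint(sfit, list(valid = TRUE,
                                                 locations = sext$locations,
                                                 values = sext$values))
        } else NULL
        params[s, ] <- parameters_per_profile(sext, strata)
        locs[s, sext$valid] <- sext$locations[sext$valid]
        if (!all(sext$valid))
          reason[s] <- paste(unique(sext$reasons[sext$reasons != ""]),
                             collapse = "+")
      }
    }
  }
  table <- cbind(meta, r_squared = r2, as.data.frame(params),
                 as.data.frame(locs),
                 discard_reason = reason, stringsAsFactors = FALSE)
  list(table = table, template = template, average_profile = avg)
}
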