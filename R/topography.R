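#' Concatenate profile sets from several images
#'
#' @param profile_list List of `ipl_profiles` objects (one per image).
#' @return A single `ipl_profiles` object with stacked rows.
#' @export
bind_profiles <- function(profile_list) {
  stopifnot(length(profile_list) >= 1,
            all(vapply(profile_list, inherits, logical(1), "ipl_profiles")))
  structure(list(
    values = do.call(rbind, lapply(profile_list, `[[`, "values")),
    meta = do.call(rbind, lapply(profile_list, `[[`, "meta"))),
    class = "ipl_profiles")
}

#' Average normalized IPL profiles by group
#'
#' Unweighted means of normalized segment profiles within groups, the three
#' averaging tiers of the analysis: `"all"` (one grand average), `"image"`
#' (one profile per image) or `"eccentricity"` (equal-width bins of
#' eccentricity magnitude). Averaging always operates on the normalized
#' 1.5-degree segment profiles so every segment carries equal weight;
#' excluded segments are dropped, and empty groups are omitted.
#'
#' @param profiles An `ipl_profiles` object (possibly from
#'   [bind_profiles()]).
#' @param by Grouping: `"all"`, `"image"`, or `"eccentricity"`.
#' @param n_bins Number of eccentricity bins (used for
#'   `by = "eccentricity"`); bin edges span `[0, max|e|]` exactly.
#' @return A list: `values` (group x 101 matrix), `groups` (data frame with
#'   group label, n segments, mean eccentricity magnitude and mean IPL
#'   thickness).
#' @export
average_profiles <- function(profiles, by = c("all", "image", "eccentricity"),
                             n_bins = 25) {
  stopifnot(inherits(profiles, "ipl_profiles"))
  by <- match.arg(by)
  keep <- !profiles$meta$excluded & !is.na(profiles$values[, 1])
  meta <- profiles$meta[keep, , drop = FALSE]
  vals <- profiles$values[keep, , drop = FALSE]
  if (!nrow(vals)) stop("no non-excluded profiles to average", call. = FALSE)
  g <- switch(by,
    all = rep("all", nrow(meta)),
    image = meta$image_id,
    eccentricity = {
      e <- abs(meta$eccentricity_mm)
      if (any(is.na(e)))
        stop("eccentricities must be assigned before binning", call. = FALSE)
      edges <- seq(0, max(e), length.out = n_bins + 1)
      as.character(pmin(findInterval(e, edges, rightmost.closed = TRUE),
                        n_bins))
    })
  idx <- split(seq_len(nrow(meta)), g)
  groups <- data.frame(
    group = names(idx),
    n = vapply(idx, length, integer(1)),
    mean_abs_eccentricity_mm = vapply(idx, function(i)
      mean(abs(meta$eccentricity_mm[i])), numeric(1)),
    mean_ipl_thickness_um = vapply(idx, function(i)
      mean(meta$mean_ipl_thickness_um[i]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  values <- t(vapply(idx, function(i) colMeans(vals[i, , drop = FALSE]),
                     numeric(101)))
  if (by == "eccentricity") {
    ord <- order(as.numeric(groups$group))
    groups <- groups[ord, , drop = FALSE]
    values <- values[ord, , drop = FALSE]
  }
  list(values = values, groups = groups)
}

#' Eccentricity-binned IPL lamination image
#'
#' Partitions segments into equal-width bins of eccentricity magnitude,
#' averages the normalized profiles and IPL thicknesses within each bin, and
#' rescales each bin's percent-axis profile to its mean IPL thickness in
#' microns. Rendered side by side, the bins form the "average appearance"
#' of the IPL in depth: both thickness and stratum contrast vary with
#' eccentricity.
#'
#' @param profiles An `ipl_profiles` object with eccentricities assigned.
#' @param n_bins Number of eccentricity bins.
#' @param depth_step_um Axial sampling of the rendered image (um).
#' @return A list: `image` (depth x bin matrix, `NA` below the local IPL),
#'   `depth_um`, `bin_centers_mm`, `mean_thickness_um`, `profiles`
#'   (bin x 101 percent-axis means).
#' @export
eccentricity_bin_image <- function(profiles, n_bins = 25,
                                   depth_step_um = 1) {
  avg <- average_profiles(profiles, by = "eccentricity", n_bins = n_bins)
  keep <- !profiles$meta$excluded & !is.na(profiles$values[, 1])
  emax <- max(abs(profiles$meta$eccentricity_mm[keep]))
  edges <- seq(0, emax, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  present <- as.numeric(avg$groups$group)
  depth <- seq(0, max(avg$groups$mean_ipl_thickness_um), by = depth_step_um)
  img <- matrix(NA_real_, length(depth), n_bins)
  for (i in seq_along(present)) {
    th <- avg$groups$mean_ipl_thickness_um[i]
    inside <- depth <= th
    img[inside, present[i]] <- stats::approx(percent_axis() / 100 * th,
                                             avg$values[i, ],
                                             xout = depth[inside])$y
  }
  list(image = img, depth_um = depth, bin_centers_mm = centers,
       mean_thickness_um = avg$groups$mean_ipl_thickness_um,
       profiles = avg$values)
}

#' Rolling-window summary of a parameter against a predictor
#'
#' Sorts segments by the predictor and reports the sliding-window mean and
#' standard error of one stratification parameter. The window is a fixed
#' number of consecutive observations in rank order (not predictor units)
#' and advances one observation at a time.
#'
#' @param table A cohort table (see [stratify_image()] /
#'   [build_cohort_table()]).
#' @param parameter One of the 14 parameter names (see output of
#'   [parameters_per_profile()]).
#' @param predictor `"ipl_thickness_um"` or `"eccentricity_mm"` (magnitude).
#' @param window Window size in observations.
#' @return Data frame: `predictor` (window mean of the predictor), `mean`,
#'   `std_error`, `n`.
#' @export
rolling_summary <- function(table, parameter,
                            predictor = c("ipl_thickness_um",
                                          "eccentricity_mm"),
                            window = 21) {
  predictor <- match.arg(predictor)
  stopifnot(parameter %in% names(table))
  x <- table[[predictor]]
  if (predictor == "eccentricity_mm") x <- abs(x)
  y <- table[[parameter]]
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(y) < window)
    stop("fewer valid rows (", length(y), ") than the window size (",
         window, ")", call. = FALSE)
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  n_out <- length(y) - window + 1
  csx <- c(0, cumsum(x))
  csy <- c(0, cumsum(y))
  csy2 <- c(0, cumsum(y^2))
  i <- seq_len(n_out)
  mean_y <- (csy[i + window] - csy[i]) / window
  var_y <- pmax(0, (csy2[i + window] - csy2[i]) / window - mean_y^2) *
    window / (window - 1)
  data.frame(predictor = (csx[i + window] - csx[i]) / window,
             mean = mean_y,
             std_error = sqrt(var_y / window),
             n = window)
}

#' Design counts and exclusion accounting for a cohort table
#'
#' @param table A cohort table.
#' @return A list: `n_subjects`, `n_images`, `n_segments`,
#'   `n_excluded_segments`, `exclusions_by_reason` (named counts over
#'   non-empty discard reasons), `n_valid_by_parameter` (non-`NA` counts for
#'   each of the 14 parameters).
#' @export
cohort_counts <- function(table) {
  if (!nrow(table))
    return(list(n_subjects = 0L, n_images = 0L, n_segments = 0L,
                n_excluded_segments = 0L,
                exclusions_by_reason = integer(0),
                n_valid_by_parameter = integer(0)))
  reasons <- table$discard_reason[!is.na(table$discard_reason) &
                                    table$discard_reason != ""]
  pn <- intersect(parameter_names(), names(table))
  list(
    n_subjects = length(unique(table$subject_id)),
    n_images = length(unique(table$image_id)),
    n_segments = nrow(table),
    n_excluded_segments = sum(table$excluded),
    exclusions_by_reason = if (length(reasons)) {
      tb <- table(reasons)
      stats::setNames(as.integer(tb), names(tb))
    } else integer(0),
    n_valid_by_parameter = vapply(pn, function(p) sum(!is.na(table[[p]])),
                                  integer(1)))
}
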