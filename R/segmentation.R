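#' Detect retinal layer boundaries by second-derivative zero crossings
#'
#' Per-column boundary detection on a background-corrected high-quality
#' image. Each depth profile is Gaussian-smoothed (axially and laterally),
#' and layer edges are located at zero crossings of the second derivative of
#' intensity: a rising edge (dark-to-bright) is a crossing where the first
#' derivative is positive, a falling edge the converse. Crossings are
#' assigned to the ILM, IPL--GCL, IPL--INL and IS/OS boundaries using the
#' expected depth ordering of bright bands (NFL, IPL, OPL, IS/OS): the ILM
#' is the first strong rising edge, the IS/OS the rising edge into the
#' brightest outer band, and the IPL is the second bright run between them.
#' Columns where the assignment fails (e.g. the foveal center, where the
#' inner layers vanish) are masked invalid.
#'
#' @param image A background-corrected `hq_image`.
#' @param axial_sigma_px,lateral_sigma_px Gaussian smoothing applied before
#'   differentiation (second derivatives amplify noise).
#' @param ilm_frac Fraction of the column's 99th percentile used to seed the
#'   ILM search.
#' @return A `layer_boundaries` data frame: `column`, sub-pixel depths
#'   `ilm`, `ipl_gcl`, `ipl_inl`, `isos` (pixel rows), and `valid`.
#' @export
detect_boundaries <- function(image, axial_sigma_px = 2,
                              lateral_sigma_px = 2, ilm_frac = 0.3) {
  stopifnot(inherits(image, "hq_image"))
  if (!isTRUE(image$provenance$background_corrected))
    warning("image does not appear to be background-corrected")
  img <- image$image
  sm <- conv_columns(img, gaussian_kernel(axial_sigma_px))
  if (lateral_sigma_px > 0)
    sm <- t(conv_columns(t(sm), gaussian_kernel(lateral_sigma_px)))
  nz <- nrow(sm)
  nx <- ncol(sm)
  out <- data.frame(column = seq_len(nx), ilm = NA_real_,
                    ipl_gcl = NA_real_, ipl_inl = NA_real_,
                    isos = NA_real_, valid = FALSE)
  for (j in seq_len(nx)) {
    y <- sm[, j]
    q99 <- stats::quantile(y, 0.99, names = FALSE)
    if (!is.finite(q99) || q99 <= 0 || stats::sd(y) < 1e-12 * max(1, q99))
      next
    d1 <- c(0, diff(y))
    d2 <- c(0, diff(y, differences = 2), 0)
    ilm_seed <- which(y > ilm_frac * q99)[1]
    if (is.na(ilm_seed) || ilm_seed < 3) next
    ilm <- refine_edge(d1, d2, ilm_seed, rising = TRUE, radius = 6)
    if (is.na(ilm)) next
    # IS/OS: brightest band well below the ILM
    lo <- min(nz - 2L, ceiling(ilm) + 10L)
    isos_center <- lo - 1L + which.max(y[lo:nz])
    isos <- refine_edge(d1, d2, isos_center, rising = TRUE, radius = 12,
                        at_most = isos_center)
    if (is.na(isos) || isos <= ilm + 10) next
    # ILM and IS/OS survive even where the inner layers vanish (foveola);
    # keep them for foveolar localization although the column stays invalid
    # until the IPL boundaries are also assigned.
    out$ilm[j] <- ilm
    out$isos[j] <- isos
    # bright/dark runs between ILM and the IS/OS rise
    span <- ceiling(ilm):floor(isos - 2)
    if (length(span) < 12) next
    ys <- y[span]
    th <- (stats::quantile(ys, 0.15, names = FALSE) +
             stats::quantile(ys, 0.85, names = FALSE)) / 2
    r <- rle(ys > th)
    starts <- span[cumsum(c(1, utils::head(r$lengths, -1)))]
    bright <- which(r$values)
    if (length(bright) != 3) next           # NFL, IPL, OPL required
    ipl_run <- bright[2]
    ipl_top_seed <- starts[ipl_run]
    ipl_bot_seed <- starts[ipl_run] + r$lengths[ipl_run]
    ipl_gcl <- refine_edge(d1, d2, ipl_top_seed, rising = TRUE, radius = 6)
    ipl_inl <- refine_edge(d1, d2, ipl_bot_seed, rising = FALSE, radius = 6)
    if (is.na(ipl_gcl) || is.na(ipl_inl)) next
    if (!(ilm < ipl_gcl && ipl_gcl < ipl_inl && ipl_inl < isos)) next
    out$ipl_gcl[j] <- ipl_gcl
    out$ipl_inl[j] <- ipl_inl
    out$valid[j] <- TRUE
  }
  if (mean(out$valid) < 0.5)
    stop("segmentation failure: boundary assignment failed in more than ",
         "half of the columns", call. = FALSE)
  class(out) <- c("layer_boundaries", "data.frame")
  out
}

# Sub-pixel edge position: the zero crossing of the second derivative d2
# nearest to `seed` whose first derivative matches the edge direction.
# d1/d2 are aligned so d1[k], d2[k] refer to row k. Returns the interpolated
# crossing position in row units, or NA.
refine_edge <- function(d1, d2, seed, rising = TRUE, radius = 6,
                        at_most = NULL) {
  n <- length(d2)
  ks <- max(2, seed - radius):min(n - 1, seed + radius)
  if (!is.null(at_most)) ks <- ks[ks <= at_most]
  cand <- ks[d2[ks] * d2[ks + 1] < 0 &
               (if (rising) d1[ks] > 0 else d1[ks] < 0) &
               (if (rising) d2[ks] > 0 else d2[ks] < 0)]
  if (!length(cand)) return(NA_real_)
  k <- cand[which.min(abs(cand - seed))]
  k + d2[k] / (d2[k] - d2[k + 1])
}

#' Apply manual boundary overrides
#'
#' Replaces detected boundary depths in selected columns with externally
#' supplied values (the file-based stand-in for interactive correction of
#' segmentation errors) and marks those columns valid. The depth-ordering
#' invariant is re-checked.
#'
#' @param boundaries A `layer_boundaries` object.
#' @param overrides Data frame with a `column` field plus any of `ilm`,
#'   `ipl_gcl`, `ipl_inl`, `isos`; `NA` entries leave the detected value in
#'   place.
#' @return The corrected `layer_boundaries`.
#' @export
apply_boundary_overrides <- function(boundaries, overrides) {
  stopifnot(inherits(boundaries, "layer_boundaries"),
            is.data.frame(overrides))
  if (nrow(overrides) == 0) return(boundaries)
  if (!"column" %in% names(overrides))
    stop("overrides need a 'column' field", call. = FALSE)
  if (any(!(overrides$column %in% boundaries$column)))
    stop("override columns outside the image width", call. = FALSE)
  for (i in seq_len(nrow(overrides))) {
    j <- match(overrides$column[i], boundaries$column)
    for (fld in intersect(c("ilm", "ipl_gcl", "ipl_inl", "isos"),
                          names(overrides))) {
      v <- overrides[[fld]][i]
      if (!is.na(v)) boundaries[[fld]][j] <- v
    }
    b <- unlist(boundaries[j, c("ilm", "ipl_gcl", "ipl_inl", "isos")])
    if (any(is.na(b)) || any(diff(b) <= 0))
      stop("invalid override: boundaries must satisfy ",
           "ILM < IPL-GCL < IPL-INL < IS/OS", call. = FALSE)
    boundaries$valid[j] <- TRUE
  }
  boundaries
}

#' Locate the foveolar center
#'
#' The foveola is the lateral position minimizing the distance between the
#' inner limiting membrane (ILM) and the photoreceptor inner/outer segment
#' junction (IS/OS). The per-column distance trace is interpolated across
#' invalid columns, smoothed laterally, and its minimum returned; ties are
#' broken toward the image center. A minimum sitting on the image edge
#' (no pit inside the field of view) raises a warning.
#'
#' @param boundaries A `layer_boundaries` object.
#' @param smooth_cols Width (columns) of the lateral smoothing kernel.
#' @return Column index (integer) of the foveolar center.
#' @export
find_foveal_center <- function(boundaries, smooth_cols = 15) {
  stopifnot(inherits(boundaries, "layer_boundaries"))
  ok <- !is.na(boundaries$ilm) & !is.na(boundaries$isos)
  if (sum(ok) < smooth_cols)
    stop("foveola not found: too few valid columns", call. = FALSE)
  nx <- nrow(boundaries)
  d <- rep(NA_real_, nx)
  d[ok] <- boundaries$isos[ok] - boundaries$ilm[ok]
  d <- stats::approx(which(!is.na(d)), d[!is.na(d)], xout = seq_len(nx),
                     rule = 2)$y
  k <- rep(1 / smooth_cols, smooth_cols)
  dsm <- conv_columns(matrix(d, ncol = 1), k)[, 1]
  mins <- which(dsm == min(dsm))
  center_col <- mins[which.min(abs(mins - (nx + 1) / 2))]
  if (center_col <= 1 || center_col >= nx)
    warning("ILM-IS/OS distance is minimal at the image edge; ",
            "no foveal pit inside the field of view")
  as.integer(center_col)
}
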