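#' Extract one A-scan's IPL profile on the percent-thickness axis
#'
#' Linearly interpolates the background-corrected intensity of one image
#' column between the IPL--GCL boundary (0%) and the IPL--INL boundary
#' (100%) onto 101 evenly spaced points (1% increments). For a 50 um IPL
#' this corresponds to a 0.5 um sampling interval.
#'
#' @param image A background-corrected `hq_image`.
#' @param boundaries A `layer_boundaries` object.
#' @param column Column index.
#' @return Numeric vector of 101 intensities, or `NULL` when the column is
#'   invalid or has non-positive IPL thickness.
#' @export
extract_column_profile <- function(image, boundaries, column) {
  stopifnot(inherits(image, "hq_image"), inherits(boundaries, "layer_boundaries"))
  j <- match(column, boundaries$column)
  if (is.na(j) || !boundaries$valid[j]) return(NULL)
  top <- boundaries$ipl_gcl[j]
  bot <- boundaries$ipl_inl[j]
  if (!is.finite(top) || !is.finite(bot) || bot <= top) return(NULL)
  z <- top + (bot - top) * percent_axis() / 100
  stats::approx(seq_len(nrow(image$image)), image$image[, column],
                xout = z, rule = 2)$y
}

#' Segment an image into transverse regions and average IPL profiles
#'
#' Partitions the image into contiguous transverse segments of fixed retinal
#' width (default 450 um, i.e. 1.5 degrees), averages the per-column percent
#' axis profiles of the valid columns in each segment, records the mean IPL
#' thickness, and normalizes each segment profile to mean intensity 1 so
#' that intensities read as contrasts relative to the IPL mean. Segments
#' whose mean IPL thickness is below `thickness_min_um` (or that contain no
#' valid column) are flagged excluded.
#'
#' @param image A background-corrected `hq_image`.
#' @param boundaries A `layer_boundaries` object.
#' @param segment_width_um Transverse segment width in um.
#' @param thickness_min_um Exclusion threshold on mean segment IPL
#'   thickness (um).
#' @return An object of class `ipl_profiles`: `values` (n_segments x 101
#'   matrix of normalized profiles; `NA` rows for empty segments) and `meta`
#'   (one row per segment: `segment_index`, `center_um` from the left image
#'   edge, `mean_ipl_thickness_um`, `n_columns`, `excluded`, `reason`,
#'   `eccentricity_mm` (filled by [assign_eccentricities()]), subject and
#'   image ids).
#' @export
segment_profiles <- function(image, boundaries, segment_width_um = 450,
                             thickness_min_um = 24) {
  stopifnot(inherits(image, "hq_image"))
  px <- image$meta$pixel_size_lateral_um
  pz <- image$meta$pixel_size_axial_um
  nx <- ncol(image$image)
  width_um <- nx * px
  n_seg <- floor(width_um / segment_width_um + 1e-9)
  if (n_seg < 1)
    stop("image narrower than one segment", call. = FALSE)
  centers_um <- (seq_len(nx) - 0.5) * px
  seg_of <- pmin(n_seg, floor(centers_um / segment_width_um) + 1L)
  thick_um <- (boundaries$ipl_inl - boundaries$ipl_gcl) * pz
  values <- matrix(NA_real_, n_seg, 101)
  meta <- data.frame(segment_index = seq_len(n_seg),
                     center_um = (seq_len(n_seg) - 0.5) * segment_width_um,
                     mean_ipl_thickness_um = NA_real_,
                     n_columns = 0L,
                     excluded = TRUE,
                     reason = "empty",
                     eccentricity_mm = NA_real_,
                     subject_id = image$meta$subject_id %||% NA_character_,
                     image_id = image$meta$image_id %||% NA_character_,
                     stringsAsFactors = FALSE)
  for (s in seq_len(n_seg)) {
    cols <- which(seg_of == s & boundaries$valid & thick_um > 0)
    if (!length(cols)) next
    prof <- vapply(cols, function(j) extract_column_profile(image, boundaries, j),
                   numeric(101))
    avg <- rowMeans(prof)
    mth <- mean(thick_um[cols])
    meta$mean_ipl_thickness_um[s] <- mth
    meta$n_columns[s] <- length(cols)
    m <- mean(avg)
    if (m <= 0) next
    values[s, ] <- avg / m
    if (mth < thickness_min_um) {
      meta$excluded[s] <- TRUE
      meta$reason[s] <- "thickness"
    } else {
      meta$excluded[s] <- FALSE
      meta$reason[s] <- ""
    }
  }
  structure(list(values = values, meta = meta), class = "ipl_profiles")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign signed eccentricities to segments
#'
#' Fills each segment's eccentricity as the signed distance (mm) from the
#' segment center to the foveolar center along the spoke. The sign encodes
#' the side of the foveola; analyses binning by eccentricity magnitude take
#' the absolute value.
#'
#' @param profiles An `ipl_profiles` object.
#' @param foveal_center_col Column index of the foveola (from
#'   [find_foveal_center()]).
#' @param pixel_size_lateral_um Lateral pixel size (um); defaults to the
#'   value recorded when the profiles were extracted, if present.
#' @return The `ipl_profiles` with `meta$eccentricity_mm` filled.
#' @export
assign_eccentricities <- function(profiles, foveal_center_col,
                                  pixel_size_lateral_um) {
  stopifnot(inherits(profiles, "ipl_profiles"))
  center_um <- (foveal_center_col - 0.5) * pixel_size_lateral_um
  profiles$meta$eccentricity_mm <-
    (profiles$meta$center_um - center_um) / 1000
  profiles
}
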