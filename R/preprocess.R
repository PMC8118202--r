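#' Estimate per-frame axial shifts by cross-correlation
#'
#' Axial (depth) motion between repeated fast frames is estimated from the
#' laterally averaged depth profile of each frame, cross-correlated against
#' the first frame over integer lags. The shift of frame 1 is 0 by
#' definition. Registration is axial-only: frames sit at distinct slow-axis
#' positions by design, so no lateral registration is attempted.
#'
#' @param stack A `frame_stack` (see [render_frame_stack()] or
#'   [read_frame_stack()]).
#' @param max_shift_px Largest |shift| searched (px).
#' @return Integer vector of per-frame axial shifts (px), first element 0.
#'   A positive shift means the frame content sits deeper than in frame 1.
#' @export
register_frames <- function(stack, max_shift_px = 12) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- dim(stack$frames)[3]
  if (nf < 2)
    stop("registration requires at least 2 frames", call. = FALSE)
  profiles <- apply(stack$frames, 3, rowMeans)      # depth x frame
  if (any(apply(profiles, 2, function(p) all(p == 0))))
    stop("registration degenerate: a frame is identically zero",
         call. = FALSE)
  ref <- profiles[, 1] - mean(profiles[, 1])
  nz <- length(ref)
  lags <- -max_shift_px:max_shift_px
  shifts <- integer(nf)
  for (f in 2:nf) {
    p <- profiles[, f] - mean(profiles[, f])
    score <- vapply(lags, function(l) {
      # frame content deeper by l: frame[z] matches ref[z - l]
      zf <- max(1, 1 + l):min(nz, nz + l)
      sum(p[zf] * ref[zf - l]) / length(zf)
    }, numeric(1))
    shifts[f] <- lags[which.max(score)]
  }
  shifts
}

#' Average registered frames into a high-quality image
#'
#' Aligns each frame by its integer axial shift (into the coordinates of
#' frame 1) and takes the per-pixel mean intensity. Depth rows not covered
#' by every frame after shifting are cropped; the crop offset is recorded in
#' the provenance so depth coordinates can be mapped back to the raw frames.
#'
#' @param stack A `frame_stack`.
#' @param shifts Integer axial shift per frame, as from [register_frames()];
#'   `NULL` means no motion correction (all zero).
#' @return An object of class `hq_image` with elements `image` (depth x
#'   lateral matrix), `meta` (inherited from the stack) and `provenance`
#'   (`n_frames`, `shifts`, `row_offset` such that output row `z`
#'   corresponds to frame-1 row `z + row_offset`, and background state).
#' @export
average_frames <- function(stack, shifts = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- dim(stack$frames)[3]
  nz <- dim(stack$frames)[1]
  if (is.null(shifts)) shifts <- integer(nf)
  if (length(shifts) != nf)
    stop("need one shift per frame", call. = FALSE)
  shifts <- as.integer(shifts)
  z0 <- max(1L, 1L - min(shifts))
  z1 <- min(nz, nz - max(shifts))
  if (z0 > z1)
    stop("shifts leave no commonly covered depth rows", call. = FALSE)
  acc <- matrix(0, z1 - z0 + 1L, dim(stack$frames)[2])
  for (f in seq_len(nf))
    acc <- acc + stack$frames[(z0:z1) + shifts[f], , f]
  structure(list(
    image = acc / nf,
    meta = stack$meta,
    provenance = list(n_frames = nf, shifts = shifts,
                      row_offset = z0 - 1L,
                      background_corrected = FALSE,
                      background_level = NA_real_)),
    class = "hq_image")
}

# Coarse per-column ILM estimate used for background-region placement when
# no segmentation is available yet: first row (of a lightly smoothed column)
# exceeding a fraction of the column's upper quantile.
coarse_ilm <- function(image, frac = 0.4) {
  sm <- conv_columns(image, gaussian_kernel(2))
  apply(sm, 2, function(col) {
    thr <- frac * stats::quantile(col, 0.99, names = FALSE)
    i <- which(col > thr)
    if (!length(i)) NA_real_ else i[1]
  })
}

#' Subtract the additive-noise background
#'
#' Estimates the additive-noise floor as the mean intensity in a vitreous
#' window above the inner limiting membrane (ILM) and subtracts it from the
#' whole image, flooring at zero. This removes the positive bias that
#' additive sensor noise contributes on top of backscattered signal.
#' Idempotent: an image whose provenance says it is already corrected is
#' returned unchanged.
#'
#' @param image An `hq_image`.
#' @param boundaries Optional `layer_boundaries` supplying the ILM; when
#'   `NULL` a coarse internal ILM estimate is used.
#' @param window_px Two integers: the vitreous window spans from
#'   `window_px[1]` to `window_px[2]` pixels above the ILM in each column.
#' @return The corrected `hq_image`; the estimated background is stored in
#'   `provenance$background_level`.
#' @export
subtract_background <- function(image, boundaries = NULL,
                                window_px = c(10, 40)) {
  stopifnot(inherits(image, "hq_image"))
  if (isTRUE(image$provenance$background_corrected)) return(image)
  ilm <- if (is.null(boundaries)) {
    coarse_ilm(image$image)
  } else {
    stopifnot(inherits(boundaries, "layer_boundaries"))
    ifelse(boundaries$valid, boundaries$ilm, NA_real_)
  }
  nz <- nrow(image$image)
  vals <- c()
  for (j in seq_along(ilm)) {
    if (is.na(ilm[j])) next
    hi <- floor(ilm[j]) - window_px[1]
    lo <- floor(ilm[j]) - window_px[2]
    if (hi < 1) next
    vals <- c(vals, image$image[max(1, lo):hi, j])
  }
  if (!length(vals))
    stop("background estimation failed: no vitreous region above the ILM",
         call. = FALSE)
  bg <- mean(vals)
  image$image <- pmax(image$image - bg, 0)
  image$provenance$background_corrected <- TRUE
  image$provenance$background_level <- bg
  image
}
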