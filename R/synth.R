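#' Configuration of the synthetic retinal phantom
#'
#' Defines the anatomy, optics and noise of a layered retinal phantom used to
#' validate the IPL stratification pipeline end to end. The phantom emulates
#' the features the analysis relies on: an IPL whose thickness vanishes at
#' the foveola, peaks at 1--2 mm eccentricity and declines gradually beyond;
#' a pentalaminar IPL reflectivity profile (three peaks S5/S3/S1, two valleys
#' S4/S2, S5 innermost) whose S5 contrast follows a downward parabola in
#' eccentricity; fully developed speckle (intensity contrast 1) decorrelated
#' across frames; additive sensor noise with a positive mean (noise floor);
#' and inter-frame axial jitter.
#'
#' @param foveal_pit_radius_mm Radius of the foveal pit over which the IPL
#'   rises from zero thickness (mm).
#' @param ipl_peak_thickness_um IPL thickness at its eccentric maximum (um).
#' @param ipl_peak_eccentricity_mm Eccentricity of the IPL thickness maximum.
#' @param ipl_decline_rate_um_per_mm Linear thinning rate beyond the peak.
#' @param ipl_edge_fraction Fraction of peak thickness reached at the pit
#'   radius (the top of the foveal slope).
#' @param stratum_fractions Five positive fractions (S5, S4, S3, S2, S1,
#'   inner to outer) of the IPL occupied by each stratum; must sum to 1.
#' @param peak_contrasts Normalized reflectivity of the three hyper-reflective
#'   strata, named S5, S3, S1 (relative to IPL mean 1). The S5 entry is used
#'   only when `s5_contrast_coeffs` is `NULL`.
#' @param valley_contrasts Normalized reflectivity of the hypo-reflective
#'   strata, named S4, S2.
#' @param s5_contrast_coeffs Coefficients `c(c0, c1, c2)` of the S5 contrast
#'   parabola `c0 + c1*e + c2*e^2` in eccentricity `e` (mm), with `c2 < 0`.
#'   See [s5_coeffs_from_vertex()].
#' @param layer_reflectivities Named mean reflectivities of the non-IPL
#'   layers (vitreous, nfl, gcl, ipl, inl, opl, onl, isos, rpe, below).
#' @param layer_thicknesses_um Named thicknesses (um) of the fixed layers and
#'   the at-peak thicknesses of the inner layers that scale with the IPL
#'   (nfl, gcl, inl scale with local IPL thickness; opl, onl, isos, rpe are
#'   constant). `z_isos_um` anchors the (flat) IS/OS band depth.
#' @param psf_fwhm_um Axial FWHM of the imaging point-spread function (um).
#' @param speckle Logical; multiply frames by fully developed speckle.
#'   Turning it off (together with zero additive noise and jitter) gives the
#'   noise-free mean reflectance image used for ground-truth recovery tests.
#' @param additive_noise_mean Mean of the additive noise floor (intensity).
#' @param additive_noise_sd Standard deviation of additive Gaussian noise.
#' @param n_frames Frames per raster scan (repeated fast frames offset along
#'   the slow axis; the phantom is invariant along the slow axis so frames
#'   differ only in speckle, jitter and noise).
#' @param frame_spacing_um Slow-axis frame spacing (metadata only).
#' @param axial_jitter_sd_px SD of the per-frame integer axial shift.
#' @param microns_per_degree Retinal scaling constant (um per degree of
#'   visual angle); 300 makes 1.5 degrees equal 450 um.
#' @param pixel_size_axial_um,pixel_size_lateral_um Pixel pitch (um).
#' @param n_depth_px,n_lateral_px Image dimensions in pixels.
#' @param oversample Axial oversampling factor used when rendering the
#'   band-limited mean reflectance image.
#' @param seed Default random seed for rendering.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(
    foveal_pit_radius_mm = 0.6,
    ipl_peak_thickness_um = 40,
    ipl_peak_eccentricity_mm = 1.5,
    ipl_decline_rate_um_per_mm = 3,
    ipl_edge_fraction = 0.85,
    stratum_fractions = c(S5 = 0.18, S4 = 0.17, S3 = 0.24, S2 = 0.23,
                          S1 = 0.18),
    peak_contrasts = c(S5 = 1.15, S3 = 1.12, S1 = 1.10),
    valley_contrasts = c(S4 = 0.88, S2 = 0.90),
    s5_contrast_coeffs = s5_coeffs_from_vertex(),
    layer_reflectivities = c(vitreous = 0, nfl = 0.9, gcl = 0.3, ipl = 0.8,
                             inl = 0.28, opl = 0.85, onl = 0.22, isos = 1.4,
                             rpe = 1.0, below = 0.05),
    layer_thicknesses_um = c(nfl = 12, gcl = 30, inl = 28, opl = 20,
                             onl = 50, isos = 12, rpe = 15, z_isos_um = 220),
    psf_fwhm_um = 1.0,
    speckle = TRUE,
    additive_noise_mean = 0.05,
    additive_noise_sd = 0.02,
    n_frames = 30,
    frame_spacing_um = 5.2,
    axial_jitter_sd_px = 1.5,
    microns_per_degree = 300,
    pixel_size_axial_um = 1.0,
    pixel_size_lateral_um = 4.5,
    n_depth_px = 256,
    n_lateral_px = 1000,
    oversample = 4,
    seed = 20260101L) {
  cfg <- list(
    foveal_pit_radius_mm = foveal_pit_radius_mm,
    ipl_peak_thickness_um = ipl_peak_thickness_um,
    ipl_peak_eccentricity_mm = ipl_peak_eccentricity_mm,
    ipl_decline_rate_um_per_mm = ipl_decline_rate_um_per_mm,
    ipl_edge_fraction = ipl_edge_fraction,
    stratum_fractions = stratum_fractions,
    peak_contrasts = peak_contrasts,
    valley_contrasts = valley_contrasts,
    s5_contrast_coeffs = s5_contrast_coeffs,
    layer_reflectivities = layer_reflectivities,
    layer_thicknesses_um = layer_thicknesses_um,
    psf_fwhm_um = psf_fwhm_um,
    speckle = isTRUE(speckle),
    additive_noise_mean = additive_noise_mean,
    additive_noise_sd = additive_noise_sd,
    n_frames = as.integer(n_frames),
    frame_spacing_um = frame_spacing_um,
    axial_jitter_sd_px = axial_jitter_sd_px,
    microns_per_degree = microns_per_degree,
    pixel_size_axial_um = pixel_size_axial_um,
    pixel_size_lateral_um = pixel_size_lateral_um,
    n_depth_px = as.integer(n_depth_px),
    n_lateral_px = as.integer(n_lateral_px),
    oversample = as.integer(oversample),
    seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  geom <- c(cfg$foveal_pit_radius_mm, cfg$ipl_peak_thickness_um,
            cfg$ipl_peak_eccentricity_mm, cfg$psf_fwhm_um,
            cfg$microns_per_degree, cfg$pixel_size_axial_um,
            cfg$pixel_size_lateral_um, cfg$n_depth_px, cfg$n_lateral_px,
            cfg$oversample)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric phantom quantities must be positive", call. = FALSE)
  if (cfg$ipl_decline_rate_um_per_mm < 0)
    stop("ipl_decline_rate_um_per_mm must be non-negative", call. = FALSE)
  f <- cfg$stratum_fractions
  if (length(f) != 5 || any(f <= 0) || abs(sum(f) - 1) > 1e-9)
    stop("stratum_fractions must be 5 positive values summing to 1",
         call. = FALSE)
  if (length(cfg$peak_contrasts) != 3 || length(cfg$valley_contrasts) != 2)
    stop("need 3 peak contrasts (S5, S3, S1) and 2 valley contrasts (S4, S2)",
         call. = FALSE)
  if (min(cfg$peak_contrasts) <= max(cfg$valley_contrasts))
    stop("peak contrasts must exceed valley contrasts", call. = FALSE)
  if (!is.null(cfg$s5_contrast_coeffs)) {
    if (length(cfg$s5_contrast_coeffs) != 3 || cfg$s5_contrast_coeffs[3] >= 0)
      stop("s5_contrast_coeffs must be (c0, c1, c2) with c2 < 0",
           call. = FALSE)
  }
  if (cfg$ipl_edge_fraction <= 0 || cfg$ipl_edge_fraction > 1)
    stop("ipl_edge_fraction must lie in (0, 1]", call. = FALSE)
  if (cfg$additive_noise_sd < 0 || cfg$additive_noise_mean < 0)
    stop("additive noise parameters must be non-negative", call. = FALSE)
  if (cfg$n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' S5 contrast parabola from vertex parameters
#'
#' Builds the coefficients `(c0, c1, c2)` of the S5 peak-contrast parabola
#' from its vertex (eccentricity and plateau value) and one point on the
#' rising flank at the foveal edge.
#'
#' @param vertex_mm Eccentricity of the contrast maximum (mm).
#' @param plateau Contrast value at the vertex.
#' @param edge_mm,edge_value Eccentricity and contrast at the foveal edge.
#' @return Numeric coefficients `c(c0, c1, c2)` with `c2 < 0`.
#' @export
s5_coeffs_from_vertex <- function(vertex_mm = 2.4, plateau = 1.2,
                                  edge_mm = 0.75, edge_value = 1.05) {
  stopifnot(edge_mm != vertex_mm, edge_value < plateau)
  c2 <- (edge_value - plateau) / (edge_mm - vertex_mm)^2
  c1 <- -2 * c2 * vertex_mm
  c0 <- plateau + c2 * vertex_mm^2
  c(c0, c1, c2)
}

#' Angular-to-retinal distance conversion
#'
#' @param degrees Visual angle in degrees.
#' @param microns_per_degree Scaling constant (default 300 um/degree, so that
#'   1.5 degrees corresponds to 450 um).
#' @return Retinal distance in microns.
#' @export
degrees_to_microns <- function(degrees, microns_per_degree = 300) {
  degrees * microns_per_degree
}

#' IPL thickness profile of the phantom
#'
#' Piecewise-smooth thickness model: zero at the foveola, a smoothstep rise
#' across the foveal pit to `ipl_edge_fraction` of the peak at the pit
#' radius, a raised-cosine shoulder up to the maximum at
#' `ipl_peak_eccentricity_mm`, and a gradual linear decline beyond
#' (floored at zero).
#'
#' @param config A [phantom_config()].
#' @param eccentricity_mm Non-negative eccentricity (mm); vectorized.
#' @return IPL thickness in microns.
#' @export
ipl_thickness_at <- function(config, eccentricity_mm) {
  stopifnot(inherits(config, "phantom_config"))
  e <- eccentricity_mm
  if (any(!is.finite(e)) || any(e < 0))
    stop("eccentricity_mm must be non-negative", call. = FALSE)
  r0 <- config$foveal_pit_radius_mm
  p <- config$ipl_peak_eccentricity_mm
  tmax <- config$ipl_peak_thickness_um
  tedge <- config$ipl_edge_fraction * tmax
  out <- numeric(length(e))
  inpit <- e <= r0
  u <- e[inpit] / r0
  out[inpit] <- tedge * (3 * u^2 - 2 * u^3)
  shoulder <- e > r0 & e <= p
  v <- (e[shoulder] - r0) / (p - r0)
  out[shoulder] <- tedge + (tmax - tedge) * (1 - cos(pi * v)) / 2
  beyond <- e > p
  out[beyond] <- pmax(0, tmax - config$ipl_decline_rate_um_per_mm *
                        (e[beyond] - p))
  out
}

# Percent-axis grid shared by the whole package: 0..100 in 1% steps.
percent_axis <- function() seq(0, 100, by = 1)

# Stratum centers (% IPL) from the configured fractions, S5 first.
stratum_centers <- function(fractions) {
  cum <- cumsum(c(0, fractions))
  100 * (cum[-length(cum)] + cum[-1]) / 2
}

# Raised-cosine interpolation basis for the true profile. The profile is
# piecewise monotone between consecutive extrema (power-cosine easing), so
# the peak-valley-peak-valley-peak template holds for any alternating target
# values and the extrema sit exactly at the stratum centers. The easing
# exponent of each inter-extremum transition is chosen so the curve crosses
# the half-way value exactly at the configured stratum boundary
# (cumulative fraction), independent of the contrast amplitudes; the
# midpoint-crossing rule therefore recovers the configured fractions on the
# true profile. Columns 1..5 weight the extrema values, column 6 the common
# edge level at 0% and 100%.
profile_phi <- function(fractions) {
  x <- percent_axis()
  mu <- stratum_centers(fractions)
  bnd <- 100 * cumsum(fractions)[1:4]      # interior stratum boundaries
  knots <- c(0, mu, 100)
  phi <- matrix(0, length(x), 6)
  for (seg in 1:6) {
    lo <- knots[seg]
    hi <- knots[seg + 1]
    gamma <- if (seg >= 2 && seg <= 5) {
      ub <- (bnd[seg - 1] - lo) / (hi - lo)
      log(0.5) / log(ub)
    } else 1
    in_seg <- if (seg == 6) x >= lo & x <= hi else x >= lo & x < hi
    u <- (1 - cos(pi * ((x[in_seg] - lo) / (hi - lo))^gamma)) / 2
    left_col <- if (seg == 1) 6L else seg - 1L
    right_col <- if (seg == 6) 6L else seg
    phi[in_seg, left_col] <- phi[in_seg, left_col] + (1 - u)
    phi[in_seg, right_col] <- phi[in_seg, right_col] + u
  }
  phi
}

# S5 peak contrast at eccentricity e (mm), clipped from below so it stays a
# peak above the valley levels. The clip only engages inside the fovea,
# where IPL thickness is below the 24 um analysis threshold anyway.
s5_contrast_at <- function(config, e) {
  if (is.null(config$s5_contrast_coeffs))
    return(rep(config$peak_contrasts[["S5"]], length(e)))
  cf <- config$s5_contrast_coeffs
  v <- cf[1] + cf[2] * e + cf[3] * e^2
  pmax(v, max(config$valley_contrasts) + 0.02)
}

# Target extrema values (5 x n) at eccentricities e: S5 peak follows the
# parabola, the rest are constant contrasts.
target_extrema_values <- function(config, e) {
  rbind(S5 = s5_contrast_at(config, e),
        S4 = rep(config$valley_contrasts[["S4"]], length(e)),
        S3 = rep(config$peak_contrasts[["S3"]], length(e)),
        S2 = rep(config$valley_contrasts[["S2"]], length(e)),
        S1 = rep(config$peak_contrasts[["S1"]], length(e)))
}

# True normalized profiles for a vector of eccentricities: 101 x n matrix.
# The extrema attain exactly the target contrasts; the common edge level at
# 0%/100% is solved per profile so the grid mean is exactly 1. If the solved
# edge level would rise above a flanking peak (deep fovea only), it is
# clipped and the profile renormalized, trading exact peak values for the
# mean-1 invariant.
true_profile_matrix <- function(config, eccentricity_mm) {
  phi <- profile_phi(config$stratum_fractions)
  w <- colMeans(phi)
  targets <- target_extrema_values(config, eccentricity_mm)   # 5 x n
  edge <- (1 - drop(w[1:5] %*% targets)) / w[6]
  edge_cap <- pmin(targets[1, ], targets[5, ]) - 0.02
  edge <- pmin(edge, edge_cap)
  p <- phi %*% rbind(targets, edge)
  sweep(p, 2, colMeans(p), "/")
}

#' True pentalaminar IPL profile at one eccentricity
#'
#' Deterministic ground-truth reflectivity profile on the 101-point
#' percent-IPL-thickness axis (0% at the IPL--GCL boundary, S5 innermost).
#' The profile has mean exactly 1, three local maxima (S5, S3, S1) and two
#' local minima (S4, S2) at the midpoints of the configured stratum
#' fractions; the S5 peak value follows the configured contrast parabola.
#'
#' @param config A [phantom_config()].
#' @param eccentricity_mm Scalar non-negative eccentricity (mm).
#' @return Numeric vector of 101 normalized reflectivities.
#' @export
true_profile_at <- function(config, eccentricity_mm) {
  stopifnot(inherits(config, "phantom_config"), length(eccentricity_mm) == 1)
  if (!is.finite(eccentricity_mm) || eccentricity_mm < 0)
    stop("eccentricity_mm must be non-negative", call. = FALSE)
  drop(true_profile_matrix(config, eccentricity_mm))
}

# Layer boundary depths (um from the image top) for a vector of absolute
# eccentricities. The IS/OS band is flat (anchored at z_isos_um); the inner
# layers (NFL, GCL, IPL, INL) scale with local IPL thickness so they vanish
# at the foveola, creating the pit. Returns a list of per-column vectors.
layer_geometry <- function(config, ecc_abs_mm) {
  th <- config$layer_thicknesses_um
  ipl <- ipl_thickness_at(config, ecc_abs_mm)
  g <- ipl / config$ipl_peak_thickness_um
  isos_top <- rep(th[["z_isos_um"]], length(ecc_abs_mm))
  onl_top <- isos_top - th[["onl"]]
  opl_top <- onl_top - th[["opl"]]
  inl_top <- opl_top - th[["inl"]] * g
  ipl_inl <- inl_top
  ipl_gcl <- ipl_inl - ipl
  gcl_top <- ipl_gcl - th[["gcl"]] * g
  ilm <- gcl_top - th[["nfl"]] * g
  list(ilm = ilm, gcl_top = gcl_top, ipl_gcl = ipl_gcl, ipl_inl = ipl_inl,
       opl_top = opl_top, onl_top = onl_top, isos_top = isos_top,
       isos_bot = isos_top + th[["isos"]],
       rpe_bot = isos_top + th[["isos"]] + th[["rpe"]],
       ipl_thickness_um = ipl)
}

# Gaussian kernel with unit sum; radius 3 sigma (at least 1).
gaussian_kernel <- function(sigma_px) {
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Convolve each column of a matrix with kernel k, replicating edges.
# Implemented as a sum of row-shifted copies: for the short kernels used
# here this is much faster than stats::filter.
conv_columns <- function(mat, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(mat)
  padded <- rbind(mat[rep(1L, r), , drop = FALSE], mat,
                  mat[rep(n, r), , drop = FALSE])
  out <- matrix(0, n, ncol(mat))
  for (i in seq_along(k))
    out <- out + k[i] * padded[i:(i + n - 1L), , drop = FALSE]
  out
}

# Noise-free mean reflectance image plus ground truth for a set of signed
# eccentricities (one per lateral column). Rendering happens on an axially
# oversampled grid, is blurred with the Gaussian PSF, then box-averaged down
# to the pixel grid, giving band-limited sub-pixel layer edges.
render_mean_image <- function(config, ecc_signed_mm) {
  nz <- config$n_depth_px
  nx <- length(ecc_signed_mm)
  ov <- config$oversample
  pz <- config$pixel_size_axial_um
  ecc_abs <- abs(ecc_signed_mm)
  geom <- layer_geometry(config, ecc_abs)
  refl <- config$layer_reflectivities
  z_hi <- (seq_len(nz * ov) - 0.5) * pz / ov
  levels <- c(refl[["vitreous"]], refl[["nfl"]], refl[["gcl"]], refl[["ipl"]],
              refl[["inl"]], refl[["opl"]], refl[["onl"]], refl[["isos"]],
              refl[["rpe"]], refl[["below"]])
  profiles <- true_profile_matrix(config, ecc_abs)   # 101 x nx
  nzh <- nz * ov
  bnames <- c("ilm", "gcl_top", "ipl_gcl", "ipl_inl", "opl_top", "onl_top",
              "isos_top", "isos_bot", "rpe_bot")
  # boundary depths -> hi-res row counts (rows with center < boundary)
  b_idx <- vapply(bnames, function(b)
    pmin(nzh, pmax(0L, as.integer(floor(geom[[b]] * ov / pz + 0.5)))),
    integer(nx))                                     # nx x 9
  b_idx <- t(apply(b_idx, 1, cummax))                # enforce ordering ties
  run_len <- apply(cbind(0L, b_idx, nzh), 1, diff)   # 10 x nx
  img <- matrix(rep(rep(levels, nx), times = as.vector(run_len)), nzh, nx)
  # pentalaminar modulation inside the IPL (between ipl_gcl and ipl_inl)
  n_ipl <- b_idx[, 4] - b_idx[, 3]
  has <- n_ipl > 0
  if (any(has)) {
    rows <- sequence(n_ipl[has]) + rep(b_idx[has, 3], n_ipl[has])
    cols <- rep(which(has), n_ipl[has])
    p <- (z_hi[rows] - geom$ipl_gcl[cols]) /
      pmax(geom$ipl_thickness_um[cols], 1e-12) * 100
    p <- pmin(pmax(p, 0), 100 - 1e-9)
    k0 <- floor(p)
    frac <- p - k0
    pv <- profiles[cbind(k0 + 1L, cols)] * (1 - frac) +
      profiles[cbind(k0 + 2L, cols)] * frac
    img[cbind(rows, cols)] <- refl[["ipl"]] * pv
  }
  sigma_hi <- config$psf_fwhm_um / 2.355 / (pz / ov)
  img <- conv_columns(img, gaussian_kernel(sigma_hi))
  img <- colMeans(array(img, dim = c(ov, nz, nx)))    # nz x nx
  # boundary depths in pixel-row coordinates (row centers at (i - 0.5) px)
  to_px <- function(um) um / pz + 0.5
  truth <- list(
    eccentricity_mm = ecc_signed_mm,
    ipl_thickness_um = geom$ipl_thickness_um,
    boundaries_px = data.frame(
      column = seq_len(nx),
      ilm = to_px(geom$ilm), ipl_gcl = to_px(geom$ipl_gcl),
      ipl_inl = to_px(geom$ipl_inl), isos = to_px(geom$isos_top)),
    extrema_locations = stratum_centers(config$stratum_fractions),
    extrema_values = target_extrema_values(config, ecc_abs),
    stratum_fractions = config$stratum_fractions)
  list(image = img, truth = truth)
}

# Unit-mean fully developed speckle field: squared modulus of a circular
# complex Gaussian field, axially correlated at the PSF scale. Pointwise the
# intensity is exponential, so the contrast (sd/mean) is exactly 1.
speckle_field <- function(nz, nx, sigma_ax_px) {
  u1 <- matrix(stats::rnorm(nz * nx), nz, nx)
  u2 <- matrix(stats::rnorm(nz * nx), nz, nx)
  if (sigma_ax_px > 0.3) {
    k <- gaussian_kernel(sigma_ax_px)
    u1 <- conv_columns(u1, k)
    u2 <- conv_columns(u2, k)
    vf <- sum(k^2)
  } else {
    vf <- 1
  }
  (u1^2 + u2^2) / (2 * vf)
}

# Shift matrix content down by s rows (deeper) with edge replication.
shift_rows <- function(mat, s) {
  if (s == 0) return(mat)
  n <- nrow(mat)
  idx <- pmin(n, pmax(1L, seq_len(n) - as.integer(s)))
  mat[idx, , drop = FALSE]
}

#' Render a synthetic B-scan frame stack
#'
#' Generates a stack of repeated fast frames of the phantom at one spoke
#' angle. Each frame is the noise-free mean reflectance image (layer stack
#' convolved axially with the Gaussian PSF), shifted by an integer axial
#' jitter, multiplied pixel-wise by unit-mean fully developed speckle
#' (independently redrawn per frame), plus additive Gaussian sensor noise
#' with a positive mean (the noise floor removed later by background
#' correction), floored at zero.
#'
#' @param config A [phantom_config()].
#' @param scan_angle_deg Spoke angle of this scan (degrees; metadata).
#' @param subject_id,image_id Identifiers carried into downstream tables.
#' @param fixation_offset_mm Displacement of the scan center from the true
#'   foveola along the spoke (mm); emulates fixation error.
#' @param seed Random seed (defaults to the config seed). Reruns with the
#'   same seed are bit-identical.
#' @return A list with elements `stack` (class `frame_stack`: `frames` array
#'   `[depth, lateral, frame]` plus `meta`) and `truth` (ground truth:
#'   per-column true eccentricity, IPL thickness, boundary rows, extremum
#'   locations/values, stratum fractions, per-frame shifts, background mean).
#' @export
render_frame_stack <- function(config, scan_angle_deg = 0,
                               subject_id = "S01", image_id = NULL,
                               fixation_offset_mm = 0,
                               seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  nz <- config$n_depth_px
  nx <- config$n_lateral_px
  set.seed(as.integer(seed))
  position_mm <- (seq_len(nx) - (nx + 1) / 2) * config$pixel_size_lateral_um / 1000
  ecc_signed <- position_mm + fixation_offset_mm
  rendered <- render_mean_image(config, ecc_signed)
  shifts <- as.integer(round(stats::rnorm(config$n_frames, 0,
                                          config$axial_jitter_sd_px)))
  sigma_ax_px <- config$psf_fwhm_um / 2.355 / config$pixel_size_axial_um
  frames <- array(0, dim = c(nz, nx, config$n_frames))
  for (f in seq_len(config$n_frames)) {
    fr <- shift_rows(rendered$image, shifts[f])
    if (config$speckle) fr <- fr * speckle_field(nz, nx, sigma_ax_px)
    fr <- fr + config$additive_noise_mean
    if (config$additive_noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(nz * nx, 0, config$additive_noise_sd),
                        nz, nx)
    frames[, , f] <- pmax(fr, 0)
  }
  if (is.null(image_id))
    image_id <- sprintf("%s_a%03d", subject_id, round(scan_angle_deg))
  stack <- structure(list(
    frames = frames,
    meta = list(pixel_size_axial_um = config$pixel_size_axial_um,
                pixel_size_lateral_um = config$pixel_size_lateral_um,
                scan_angle_deg = scan_angle_deg,
                position_mm = position_mm,
                subject_id = subject_id, image_id = image_id,
                n_frames = config$n_frames,
                frame_spacing_um = config$frame_spacing_um)),
    class = "frame_stack")
  truth <- rendered$truth
  truth$shifts_px <- shifts
  truth$background_mean <- config$additive_noise_mean
  truth$fixation_offset_mm <- fixation_offset_mm
  list(stack = stack, truth = truth)
}

#' Render a synthetic cohort of radial scans
#'
#' Draws per-subject anatomical parameters from between-subject normal
#' distributions, then renders one frame stack per subject and spoke angle
#' (angles at 30-degree intervals). Each image receives an independent
#' fixation-error offset of the scan center along its spoke. All randomness
#' derives from the master seed.
#'
#' @param config Baseline [phantom_config()] shared by the cohort.
#' @param n_subjects Number of subjects (eyes).
#' @param n_angles Number of spoke angles; `n_angles * 30 <= 180`.
#' @param subject_sd Named list of between-subject standard deviations:
#'   `ipl_peak_thickness_um`, `s5_plateau`, `s5_vertex_mm`, `fraction_sd`.
#'   Zero SDs give identical subjects.
#' @param fixation_sd_mm SD of the per-image fixation-error offset (mm).
#' @param seed Master seed.
#' @param process Optional `function(stack, truth)` applied to each rendered
#'   stack; when supplied only its results are kept, so arbitrarily large
#'   cohorts can be processed in constant memory. When `NULL` the stacks and
#'   truths themselves are returned.
#' @return A list with `subjects` (per-subject parameter table), `manifest`
#'   (per-image subject, angle, fixation offset, seed) and either
#'   `stacks`/`truths` or `results` (the `process` outputs).
#' @export
render_cohort <- function(config, n_subjects = 16, n_angles = 6,
                          subject_sd = list(ipl_peak_thickness_um = 3,
                                            s5_plateau = 0.03,
                                            s5_vertex_mm = 0.2,
                                            fraction_sd = 0.01),
                          fixation_sd_mm = 0.1,
                          seed = config$seed,
                          process = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_angles * 30 > 180)
    stop("n_angles * 30 degrees must not exceed 180", call. = FALSE)
  set.seed(as.integer(seed))
  n_images <- n_subjects * n_angles
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    ipl_peak_thickness_um = config$ipl_peak_thickness_um +
      stats::rnorm(n_subjects, 0, subject_sd$ipl_peak_thickness_um),
    s5_plateau = 1.2 + stats::rnorm(n_subjects, 0, subject_sd$s5_plateau),
    s5_vertex_mm = 2.4 + stats::rnorm(n_subjects, 0, subject_sd$s5_vertex_mm))
  frac_jitter <- matrix(stats::rnorm(5 * n_subjects, 0,
                                     subject_sd$fraction_sd), 5, n_subjects)
  offsets <- stats::rnorm(n_images, 0, fixation_sd_mm)
  stack_seeds <- sample.int(.Machine$integer.max - 1L, n_images)
  angles <- seq(0, by = 30, length.out = n_angles)
  manifest <- data.frame(
    subject_id = rep(subjects$subject_id, each = n_angles),
    scan_angle_deg = rep(angles, times = n_subjects),
    fixation_offset_mm = offsets,
    seed = stack_seeds)
  manifest$image_id <- sprintf("%s_a%03d", manifest$subject_id,
                               manifest$scan_angle_deg)
  results <- vector("list", n_images)
  stacks <- if (is.null(process)) vector("list", n_images) else NULL
  truths <- if (is.null(process)) vector("list", n_images) else NULL
  for (i in seq_len(n_images)) {
    s <- match(manifest$subject_id[i], subjects$subject_id)
    cfg_s <- config
    cfg_s$ipl_peak_thickness_um <- subjects$ipl_peak_thickness_um[s]
    cfg_s$s5_contrast_coeffs <- s5_coeffs_from_vertex(
      vertex_mm = subjects$s5_vertex_mm[s], plateau = subjects$s5_plateau[s])
    f <- pmax(config$stratum_fractions + frac_jitter[, s], 0.05)
    cfg_s$stratum_fractions <- f / sum(f)
    rs <- render_frame_stack(cfg_s, scan_angle_deg = manifest$scan_angle_deg[i],
                             subject_id = manifest$subject_id[i],
                             image_id = manifest$image_id[i],
                             fixation_offset_mm = manifest$fixation_offset_mm[i],
                             seed = manifest$seed[i])
    if (is.null(process)) {
      stacks[[i]] <- rs$stack
      truths[[i]] <- rs$truth
    } else {
      results[[i]] <- process(rs$stack, rs$truth)
    }
  }
  out <- list(subjects = subjects, manifest = manifest)
  if (is.null(process)) {
    out$stacks <- stacks
    out$truths <- truths
  } else {
    out$results <- results
  }
  out
}
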