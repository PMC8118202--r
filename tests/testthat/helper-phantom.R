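# Shared fixtures: reduced-size phantom configurations keep the unit tests
# fast; the acceptance suite uses full-size images where the check demands
# it. "Noise-free" = no speckle, no additive noise, no axial jitter, one
# frame (the mean reflectance image itself).

small_config <- function(...) {
  args <- utils::modifyList(
    list(n_depth_px = 128, pixel_size_axial_um = 2, n_lateral_px = 500,
         pixel_size_lateral_um = 9, oversample = 2),
    list(...))
  do.call(phantom_config, args)
}

small_noisefree <- function(...) {
  small_config(n_frames = 1, speckle = FALSE, additive_noise_sd = 0,
               axial_jitter_sd_px = 0, ...)
}

full_noisefree <- function(...) {
  phantom_config(n_frames = 1, speckle = FALSE, additive_noise_sd = 0,
                 axial_jitter_sd_px = 0, ...)
}

# One processed noise-free small image, cached across tests.
cached_small_run <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      rs <- render_frame_stack(small_noisefree(), seed = 4101)
      val <<- list(rendered = rs, processed = process_stack(rs$stack))
    }
    val
  }
})

# One processed noise-free full-size image (256 x 1000, 1 um axial pixels)
# for the sub-pixel boundary accuracy checks.
cached_full_run <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      rs <- render_frame_stack(full_noisefree(), seed = 4201)
      val <<- list(rendered = rs, processed = process_stack(rs$stack))
    }
    val
  }
})

# Piecewise-smooth synthetic profile through given extrema, for tests that
# need full control over peak/valley placement (monotone spline between
# anchor points).
anchored_profile <- function(locations, values, edge = c(0.95, 0.95)) {
  x <- c(0, locations, 100)
  y <- c(edge[1], values, edge[2])
  f <- stats::splinefun(x, y, method = "monoH.FC")
  f(percent_axis_grid())
}

percent_axis_grid <- function() seq(0, 100, by = 1)

# Independent brute-force oracle for constrained extrema detection:
# enumerate all interior grid extrema by neighbor comparison, greedily keep
# by decreasing prominence subject to the minimum-separation rule, then
# demand the alternating peak-valley template. Written against the same
# rules as the package but as plain enumeration.
oracle_extrema <- function(v, min_sep = 26) {
  i <- 2:100
  gmax <- i[v[i] > v[i - 1] & v[i] > v[i + 1]] - 1L
  gmin <- i[v[i] < v[i - 1] & v[i] < v[i + 1]] - 1L
  # valleys outside the outermost peaks are border troughs, not strata
  if (length(gmax)) gmin <- gmin[gmin > min(gmax) & gmin < max(gmax)]
  keep <- function(locs, vals, maxima) {
    ord <- order(if (maxima) -vals else vals, locs)
    kept <- integer(0)
    for (k in ord)
      if (!length(kept) || min(abs(locs[k] - kept)) >= min_sep)
        kept <- c(kept, locs[k])
    sort(kept)
  }
  mx <- keep(gmax, v[gmax + 1L], TRUE)
  mn <- keep(gmin, v[gmin + 1L], FALSE)
  if (length(mx) != 3 || length(mn) != 2)
    return(list(valid = FALSE))
  locs <- sort(c(mx, mn))
  if (!identical(locs, c(mx[1], mn[1], mx[2], mn[2], mx[3])))
    return(list(valid = FALSE))
  list(valid = TRUE, locations = as.numeric(locs), values = v[locs + 1L])
}

# Random degree-14 polynomial profile on the percent grid.
random_poly14 <- function() {
  x <- percent_axis_grid()
  basis <- cbind(1, stats::poly(x, 14))
  as.numeric(basis %*% c(1, stats::rnorm(14, sd = 0.4)))
}

# Synthetic subject-level parameter table for the statistics module:
# y = intercept + slope*x (+ quad*x^2) per subject, subject slopes jittered
# with SD tau, residual SD sigma.
sim_subject_table <- function(n_subjects = 16, n_segments = 40,
                              intercept = 1, slope = 0, quad = 0,
                              tau = 0, sigma = 0.05,
                              xlim = c(0.5, 3.75)) {
  do.call(rbind, lapply(seq_len(n_subjects), function(s) {
    x <- stats::runif(n_segments, xlim[1], xlim[2])
    b <- slope + stats::rnorm(1, 0, tau)
    y <- intercept + b * x + quad * x^2 + stats::rnorm(n_segments, 0, sigma)
    data.frame(subject_id = sprintf("S%02d", s), eccentricity_mm = x,
               ipl_thickness_um = stats::runif(n_segments, 25, 45),
               S5 = y, tr_S4S5 = y)
  }))
}
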