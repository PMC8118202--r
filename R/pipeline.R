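#' Process one frame stack through the full image pipeline
#'
#' Registration, intensity averaging, background correction, layer
#' segmentation, foveolar localization, percent-axis profile extraction and
#' template-guided stratification, in order.
#'
#' @param stack A `frame_stack`.
#' @param segment_width_um Transverse segment width (um).
#' @param thickness_min_um Segment exclusion threshold (um).
#' @param axial_sigma_px,lateral_sigma_px Segmentation smoothing.
#' @param boundary_overrides Optional override table
#'   ([apply_boundary_overrides()]).
#' @return A list: `image` (`hq_image`), `boundaries`, `foveal_center_col`,
#'   `profiles` (`ipl_profiles`), `table` (per-segment results),
#'   `template`, `average_profile`.
#' @export
process_stack <- function(stack, segment_width_um = 450,
                          thickness_min_um = 24,
                          axial_sigma_px = 2, lateral_sigma_px = 2,
                          boundary_overrides = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- dim(stack$frames)[3]
  shifts <- if (nf > 1) register_frames(stack) else 0L
  img <- average_frames(stack, shifts)
  img <- subtract_background(img)
  boundaries <- detect_boundaries(img, axial_sigma_px = axial_sigma_px,
                                  lateral_sigma_px = lateral_sigma_px)
  if (!is.null(boundary_overrides))
    boundaries <- apply_boundary_overrides(boundaries, boundary_overrides)
  fc <- find_foveal_center(boundaries)
  profiles <- segment_profiles(img, boundaries,
                               segment_width_um = segment_width_um,
                               thickness_min_um = thickness_min_um)
  profiles <- assign_eccentricities(profiles, fc,
                                    img$meta$pixel_size_lateral_um)
  st <- stratify_image(profiles)
  list(image = img, boundaries = boundaries, foveal_center_col = fc,
       profiles = profiles, table = st$table, template = st$template,
       average_profile = st$average_profile)
}

#' Assemble a long-format cohort table from processed images
#'
#' One row per segment, keyed by subject, image and segment, with
#' eccentricity, IPL thickness, fit R^2, the 14 stratification parameters
#' and discard bookkeeping.
#'
#' @param results List of [process_stack()] outputs (or their `table`
#'   components).
#' @return A `data.frame` cohort table.
#' @export
build_cohort_table <- function(results) {
  tabs <- lapply(results, function(r) if (is.data.frame(r)) r else r$table)
  tab <- do.call(rbind, tabs)
  tab$ipl_thickness_um <- tab$mean_ipl_thickness_um
  rownames(tab) <- NULL
  tab
}

#' Render and analyse a synthetic cohort in one pass
#'
#' Renders each subject/angle frame stack of a synthetic cohort and
#' immediately processes it through the image pipeline (constant memory:
#' stacks are discarded once analysed). Returns the cohort table, the
#' pooled segment profiles, the ground truths, and the design bookkeeping.
#'
#' @param config Baseline [phantom_config()].
#' @param n_subjects,n_angles,subject_sd,fixation_sd_mm,seed Passed to
#'   [render_cohort()].
#' @param ... Additional arguments for [process_stack()].
#' @return A list: `table` (cohort table), `profiles` (pooled
#'   `ipl_profiles`), `truths`, `subjects`, `manifest`, `counts`.
#' @export
run_cohort_pipeline <- function(config, n_subjects = 16, n_angles = 6,
                                subject_sd = list(ipl_peak_thickness_um = 3,
                                                  s5_plateau = 0.03,
                                                  s5_vertex_mm = 0.2,
                                                  fraction_sd = 0.01),
                                fixation_sd_mm = 0.1,
                                seed = config$seed, ...) {
  truths <- list()
  co <- render_cohort(config, n_subjects = n_subjects, n_angles = n_angles,
                      subject_sd = subject_sd,
                      fixation_sd_mm = fixation_sd_mm, seed = seed,
                      process = function(stack, truth) {
                        r <- process_stack(stack, ...)
                        list(table = r$table, profiles = r$profiles,
                             truth = truth,
                             foveal_center_col = r$foveal_center_col)
                      })
  table <- build_cohort_table(lapply(co$results, `[[`, "table"))
  profiles <- bind_profiles(lapply(co$results, `[[`, "profiles"))
  list(table = table, profiles = profiles,
       truths = lapply(co$results, `[[`, "truth"),
       foveal_centers = vapply(co$results, `[[`, numeric(1),
                               "foveal_center_col"),
       subjects = co$subjects, manifest = co$manifest,
       counts = cohort_counts(table))
}

#' Configuration of an end-to-end pipeline run
#'
#' @param phantom A [phantom_config()] (the simulated acquisition).
#' @param n_subjects,n_angles Cohort design.
#' @param seed Master seed for all randomness.
#' @param segment_width_um,thickness_min_um Segmentation of profiles.
#' @param rolling_window Window for rolling summaries.
#' @param n_eccentricity_bins Bins for the topographic image.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_config(),
                            n_subjects = 16, n_angles = 6,
                            seed = phantom$seed,
                            segment_width_um = 450,
                            thickness_min_um = 24,
                            rolling_window = 21,
                            n_eccentricity_bins = 25) {
  structure(list(phantom = phantom, n_subjects = n_subjects,
                 n_angles = n_angles, seed = as.integer(seed),
                 segment_width_um = segment_width_um,
                 thickness_min_um = thickness_min_um,
                 rolling_window = rolling_window,
                 n_eccentricity_bins = n_eccentricity_bins),
            class = "pipeline_config")
}

#' Run the full pipeline and write a versioned artifact directory
#'
#' Simulates the cohort, processes every image, and writes the cohort
#' table, pooled profiles, model summary and counts, plus a manifest with a
#' content hash for every output file. Reruns with the same seed are
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest path, invisibly; artifacts are written to
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message("simulate+process: ", config$n_subjects, " subjects x ",
          config$n_angles, " angles")
  res <- run_cohort_pipeline(config$phantom, config$n_subjects,
                             config$n_angles, seed = config$seed,
                             segment_width_um = config$segment_width_um,
                             thickness_min_um = config$thickness_min_um)
  message("segments: ", res$counts$n_segments, " (",
          res$counts$n_excluded_segments, " excluded)")
  files <- character(0)
  f <- file.path(out_dir, "cohort_table.csv")
  write_cohort_table(res$table, f)
  files <- c(files, f)
  prof_tab <- cbind(res$profiles$meta,
                    as.data.frame(res$profiles$values) |>
                      stats::setNames(sprintf("p%03d", 0:100)))
  f <- file.path(out_dir, "profiles.csv")
  write_cohort_table(prof_tab, f)
  files <- c(files, f)
  message("fitting 56 subject-level models")
  models <- fit_all_models(res$table)
  f <- file.path(out_dir, "model_summary.csv")
  write_cohort_table(models, f)
  files <- c(files, f)
  f <- file.path(out_dir, "counts.json")
  jsonlite::write_json(res$counts, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  f <- file.path(out_dir, "config.yaml")
  write_run_config(unclass(rapply(config, unclass, how = "replace")), f)
  files <- c(files, f)
  manifest <- file.path(out_dir, "manifest.json")
  write_manifest(files, manifest,
                 extra = list(seed = config$seed,
                              n_images = res$counts$n_images))
  invisible(manifest)
}
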