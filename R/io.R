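#' Write a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are written as 32-bit TIFF pages, scaled into `[0, 1]` by a
#' power-of-two factor; the scale and all acquisition metadata go to a JSON
#' sidecar next to the TIFF (TIFF tags are dialect-fragile across readers).
#' Intensities survive a roundtrip to the 32-bit sample quantization
#' (relative error under 1e-8 of full scale).
#'
#' @param stack A `frame_stack`.
#' @param path Output path (`.tif`); the sidecar gets the extension
#'   `.json`.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  # power-of-two scale: the division is exact in binary floating point, so
  # the only loss is the 32-bit sample quantization of the TIFF itself
  # (relative error below 1e-8 of full scale per roundtrip)
  scale <- 2^ceiling(log2(max(stack$frames, 1e-12)))
  pages <- lapply(seq_len(dim(stack$frames)[3]), function(f)
    stack$frames[, , f] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- stack$meta
  meta$intensity_scale <- scale
  meta$dim <- dim(stack$frames)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Read a frame stack written by [write_frame_stack()]
#'
#' @param path Path to the multi-page TIFF.
#' @return A `frame_stack`.
#' @export
read_frame_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("metadata sidecar missing: ", sp,
         " (needs pixel sizes, positions, ids, intensity_scale)",
         call. = FALSE)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  required <- c("pixel_size_axial_um", "pixel_size_lateral_um",
                "position_mm", "subject_id", "image_id", "intensity_scale")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("metadata sidecar lacks fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1)
    stop("frames disagree in shape", call. = FALSE)
  frames <- array(0, dim = c(dims[[1]], length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]]
  frames <- frames * meta$intensity_scale
  meta$intensity_scale <- NULL
  meta$dim <- NULL
  structure(list(frames = frames, meta = meta), class = "frame_stack")
}

#' Write a table as CSV preserving full double precision
#'
#' Numeric columns are formatted with 17 significant digits so a roundtrip
#' through [read_cohort_table()] reproduces the doubles exactly.
#'
#' @param table A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  out <- table
  for (cn in names(out))
    if (is.numeric(out[[cn]]) && !is.integer(out[[cn]]))
      out[[cn]] <- ifelse(is.na(out[[cn]]), "",
                          sprintf("%.17g", out[[cn]]))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort table CSV
#'
#' @param path CSV path written by [write_cohort_table()].
#' @return A data frame with numeric columns restored.
#' @export
read_cohort_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a run configuration as YAML
#'
#' @param config A list (e.g. [pipeline_config()]).
#' @param path YAML path.
#' @return `path` (write) or the configuration list (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

# Manifest: every output file with its md5 content hash.
write_manifest <- function(files, path, extra = list()) {
  entries <- lapply(files, function(f)
    list(file = basename(f), md5 = unname(tools::md5sum(f)),
         bytes = file.size(f)))
  jsonlite::write_json(c(extra, list(outputs = entries)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
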