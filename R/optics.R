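#' Broadband light-source specification
#'
#' Describes the OCT light source by its central wavelength and
#' full-width-at-half-maximum (FWHM) bandwidth, together with the group
#' refractive index of the imaged tissue. The coherence length of the source
#' sets the nominal axial resolution of the system.
#'
#' @param center_wavelength_nm Central wavelength of the source in nm.
#' @param fwhm_bandwidth_nm FWHM spectral bandwidth in nm. Must be positive
#'   and smaller than the central wavelength.
#' @param tissue_group_index Group refractive index of tissue, in `[1, 2]`.
#'   Default 1.35 (retinal tissue).
#' @return An object of class `source_spec`.
#' @examples
#' src <- source_spec(565, 100)
#' axial_resolution_air(src)
#' @export
source_spec <- function(center_wavelength_nm, fwhm_bandwidth_nm,
                        tissue_group_index = 1.35) {
  if (!is.numeric(center_wavelength_nm) || length(center_wavelength_nm) != 1 ||
      !is.finite(center_wavelength_nm) || center_wavelength_nm <= 0)
    stop("center_wavelength_nm must be a positive number", call. = FALSE)
  if (!is.numeric(fwhm_bandwidth_nm) || length(fwhm_bandwidth_nm) != 1 ||
      !is.finite(fwhm_bandwidth_nm) || fwhm_bandwidth_nm <= 0)
    stop("fwhm_bandwidth_nm must be a positive number", call. = FALSE)
  if (fwhm_bandwidth_nm >= center_wavelength_nm)
    stop("fwhm_bandwidth_nm must be smaller than center_wavelength_nm",
         call. = FALSE)
  if (!is.numeric(tissue_group_index) || length(tissue_group_index) != 1 ||
      !is.finite(tissue_group_index) ||
      tissue_group_index < 1 || tissue_group_index > 2)
    stop("tissue_group_index must lie in [1, 2]", call. = FALSE)
  structure(
    list(center_wavelength_nm = center_wavelength_nm,
         fwhm_bandwidth_nm = fwhm_bandwidth_nm,
         tissue_group_index = tissue_group_index),
    class = "source_spec"
  )
}

#' @rdname source_spec
#' @param x,... Passed to the print method.
#' @method print source_spec
#' @export
print.source_spec <- function(x, ...) {
  cat(sprintf(
    "OCT source: lambda0 = %g nm, FWHM bandwidth = %g nm, n_tissue = %g\n",
    x$center_wavelength_nm, x$fwhm_bandwidth_nm, x$tissue_group_index))
  cat(sprintf("  axial resolution: %.2f um (air), %.2f um (tissue)\n",
              axial_resolution_air(x), axial_resolution_tissue(x)))
  invisible(x)
}

#' OCT axial resolution in air
#'
#' FWHM axial resolution of an OCT system in air, from the coherence length
#' of a Gaussian-spectrum source: `0.44 * lambda0^2 / dlambda`, where
#' `lambda0` is the central wavelength and `dlambda` the FWHM bandwidth.
#' Wavelengths are supplied in nm; the result is returned in microns.
#'
#' @param source A [source_spec()] object.
#' @return Axial FWHM resolution in microns (full precision; round to one
#'   decimal for reporting).
#' @export
axial_resolution_air <- function(source) {
  stopifnot(inherits(source, "source_spec"))
  0.44 * source$center_wavelength_nm^2 / source$fwhm_bandwidth_nm / 1000
}

#' OCT axial resolution in tissue
#'
#' Axial resolution in tissue: the in-air value divided by the tissue group
#' refractive index.
#'
#' @inheritParams axial_resolution_air
#' @return Axial FWHM resolution in tissue, in microns.
#' @export
axial_resolution_tissue <- function(source) {
  stopifnot(inherits(source, "source_spec"))
  axial_resolution_air(source) / source$tissue_group_index
}
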