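#' CT volume container
#'
#' A `ct_volume` wraps a 3D grid of Hounsfield units together with the
#' acquisition geometry needed for calcium quantification. The array is
#' indexed `(slice, row, col)`; voxel centres sit at physical coordinates
#' `((i-1) * slice_increment, (j-1) * pixel_size, (k-1) * pixel_size)` mm,
#' so overlapping thin-slice reconstructions (e.g. 1 mm slices every
#' 0.75 mm) are represented by `slice_thickness > slice_increment`.
#'
#' Voxel volume for all quantification in this package is
#' `pixel_size^2 * slice_increment`: the increment, not the thickness, is
#' the through-plane dimension, because consecutive reconstructed slices
#' tile space at the increment.
#'
#' @param voxels Numeric 3D array of HU, dimension (slices, rows, cols).
#' @param pixel_size In-plane pixel edge length, mm.
#' @param slice_increment Distance between consecutive slice centres, mm.
#' @param slice_thickness Reconstructed slice thickness, mm. Defaults to the
#'   increment (contiguous slices). Must be >= `slice_increment`.
#' @param tube_voltage Tube voltage in kV (120 for native calcium scoring,
#'   typically 100 for contrast-enhanced TAVI planning scans). Metadata only.
#' @param modality `"native"` or `"contrast"`.
#'
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 8, 8)), pixel_size = 0.5,
#'                  slice_increment = 0.75, slice_thickness = 1,
#'                  tube_voltage = 120, modality = "native")
#' dim(vol$voxels)
#' @export
ct_volume <- function(voxels, pixel_size, slice_increment,
                      slice_thickness = slice_increment,
                      tube_voltage = NA_real_,
                      modality = c("native", "contrast")) {
  modality <- match.arg(modality)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    abort("`voxels` must be a 3D array (slice, row, col).")
  }
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels))) abort("All HU values must be finite.")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    abort("`pixel_size` must be a single positive number (mm).")
  }
  if (!is.numeric(slice_increment) || length(slice_increment) != 1L ||
      slice_increment <= 0) {
    abort("`slice_increment` must be a single positive number (mm).")
  }
  if (slice_thickness < slice_increment) {
    abort("`slice_thickness` must be >= `slice_increment`.")
  }
  structure(
    list(
      voxels = voxels,
      pixel_size = as.numeric(pixel_size),
      slice_increment = as.numeric(slice_increment),
      slice_thickness = as.numeric(slice_thickness),
      tube_voltage = as.numeric(tube_voltage),
      modality = modality
    ),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %s  %d x %d x %d voxels (slice, row, col)\n",
    x$modality, d[1], d[2], d[3]
  ))
  cat(sprintf(
    "  pixel %.3g mm, increment %.3g mm, thickness %.3g mm, %s kV\n",
    x$pixel_size, x$slice_increment, x$slice_thickness,
    ifelse(is.na(x$tube_voltage), "?", format(x$tube_voltage))
  ))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Voxel volume of a CT grid
#'
#' `pixel_size^2 * slice_increment`, in mm^3.
#'
#' @param volume A [ct_volume].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(volume) {
  stopifnot(inherits(volume, "ct_volume"))
  volume$pixel_size^2 * volume$slice_increment
}

#' Mask out adjacent calcified structures
#'
#' Reproduces the manual exclusion step of valve scoring: voxels covered by
#' the exclusion mask (coronary ostia, aortic-wall plaque, ...) are set to
#' air (-1024 HU) so that no downstream threshold can select them.
#'
#' @param volume A [ct_volume].
#' @param exclusion Logical (or 0/1) array congruent with `volume$voxels`;
#'   `TRUE` marks voxels to remove. `NULL` is a no-op.
#' @return The volume with excluded voxels set to -1024 HU.
#' @export
apply_exclusion <- function(volume, exclusion) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.null(exclusion)) return(volume)
  if (!identical(dim(exclusion), dim(volume$voxels))) {
    abort("Exclusion mask shape does not match the volume.")
  }
  keep <- volume$voxels
  keep[as.logical(exclusion)] <- -1024
  volume$voxels <- keep
  volume
}

# shared guard for mask arguments
check_mask <- function(mask, volume, what) {
  if (is.null(mask)) return(NULL)
  if (!identical(dim(mask), dim(volume$voxels))) {
    abort(sprintf("%s mask shape does not match the volume.", what))
  }
  array(as.logical(mask), dim = dim(mask))
}
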