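#' Read a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file into a [ct_volume]. Spacing comes from the
#' NIfTI `pixdim`; modality, slice thickness and tube voltage come from the
#' JSON sidecar written by [write_volume] (same path with a `.json`
#' extension) when present. A file whose header carries no usable spacing
#' (unit pixdim with unset qform/sform, or non-positive pixdim) and no
#' sidecar is rejected rather than silently defaulted.
#'
#' In-plane pixels must be square; the NIfTI grid is stored (x = col,
#' y = row, z = slice) and is permuted to the package's (slice, row, col)
#' convention on read.
#'
#' @param path Path to a NIfTI file.
#' @return A [ct_volume].
#' @seealso [write_volume]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such file: %s", path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) abort("Expected a 3D NIfTI volume.")
  hdr <- RNifti::niftiHeader(img)
  side <- sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL

  pd <- hdr$pixdim[2:4]
  if (is.null(meta)) {
    unset <- (hdr$qform_code == 0 && hdr$sform_code == 0 && all(pd == 1))
    if (unset || any(pd <= 0)) {
      abort(paste0(
        "NIfTI file carries no spacing metadata (pixdim unset) and no JSON ",
        "sidecar was found; refusing to guess voxel spacing."
      ))
    }
    pixel_size <- pd[1]
    slice_increment <- pd[3]
    slice_thickness <- pd[3]
    tube_voltage <- NA_real_
    modality <- "native"
  } else {
    pixel_size <- meta$pixel_size
    slice_increment <- meta$slice_increment
    slice_thickness <- meta$slice_thickness
    tube_voltage <- if (is.null(meta$tube_voltage)) NA_real_ else meta$tube_voltage
    modality <- meta$modality
  }
  if (abs(pd[1] - pd[2]) > 1e-6 * max(pd[1], pd[2])) {
    abort("Anisotropic in-plane pixels are not supported.")
  }
  vox <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 2, 1))
  ct_volume(vox,
    pixel_size = pixel_size, slice_increment = slice_increment,
    slice_thickness = slice_thickness, tube_voltage = tube_voltage,
    modality = modality
  )
}

#' Write a CT volume to NIfTI
#'
#' Writes voxels as double-precision NIfTI (bit-exact round trip) with
#' `pixdim = (pixel, pixel, increment)`, plus a JSON sidecar carrying slice
#' thickness, tube voltage and modality, which the NIfTI-1 header cannot
#' represent.
#'
#' @param volume A [ct_volume].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(aperm(volume$voxels, c(3, 2, 1)))
  RNifti::`pixdim<-`(img, c(volume$pixel_size, volume$pixel_size,
                            volume$slice_increment))
  RNifti::writeNifti(img, path, datatype = "double")
  jsonlite::write_json(
    list(
      pixel_size = volume$pixel_size,
      slice_increment = volume$slice_increment,
      slice_thickness = volume$slice_thickness,
      tube_voltage = volume$tube_voltage,
      modality = volume$modality
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Read a paired-measurement cohort table
#'
#' Reads a CSV with columns `id`, `native_agatston`, `cect_volume_mm3` and
#' optionally `calc_agatston` into a typed tibble. Malformed rows (negative
#' volumes, non-numeric cells) are reported with their row numbers;
#' duplicate subject ids are rejected.
#'
#' @param path CSV path.
#' @return A tibble, one row per subject.
#' @export
read_cohort <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "native_agatston", "cect_volume_mm3")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    abort(sprintf("Cohort CSV is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  as_num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  out <- tibble(
    id = raw$id,
    native_agatston = as_num("native_agatston"),
    cect_volume_mm3 = as_num("cect_volume_mm3")
  )
  if ("calc_agatston" %in% names(raw)) out$calc_agatston <- as_num("calc_agatston")
  bad_num <- which(is.na(out$native_agatston) | is.na(out$cect_volume_mm3))
  if (length(bad_num)) {
    abort(sprintf("Non-numeric measurement in cohort row(s): %s",
                  paste(bad_num, collapse = ", ")))
  }
  bad_vol <- which(out$cect_volume_mm3 < 0)
  if (length(bad_vol)) {
    abort(sprintf("Negative CECT volume in cohort row(s): %s",
                  paste(bad_vol, collapse = ", ")))
  }
  if (anyDuplicated(out$id)) abort("Duplicate subject ids in cohort table.")
  out
}

#' Write a cohort table to CSV
#'
#' @param cohort Tibble as returned by [read_cohort] or [make_paired_cohort].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Write an agreement report to JSON
#'
#' Serializes an agreement report (see [validate_conversion]) to JSON and
#' checks it against the schema shipped at
#' `system.file("extdata", "report-schema.json", package = "avcscore")`.
#'
#' @param report An `avc_agreement` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "avc_agreement"))
  payload <- list(
    n = report$n,
    icc = report$icc$estimate,
    icc_ci_low = report$icc$conf_low,
    icc_ci_high = report$icc$conf_high,
    icc_p_value = report$icc$p_value,
    icc_form = report$icc$form,
    r2 = report$r2,
    bias = report$bland_altman$bias,
    loa_lower = report$bland_altman$loa_lower,
    loa_upper = report$bland_altman$loa_upper,
    prop_bias_slope = report$bland_altman$prop_bias_slope,
    prop_bias_p = report$bland_altman$prop_bias_p,
    difference_convention = "native_minus_calculated",
    model = list(intercept = report$model$intercept, slope = report$model$slope)
  )
  validate_report_schema(payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

# minimal structural validation against the shipped schema: required keys
# present and of the declared JSON type
validate_report_schema <- function(payload) {
  schema_file <- system.file("extdata", "report-schema.json", package = "avcscore")
  schema <- jsonlite::read_json(schema_file, simplifyVector = FALSE)
  for (key in schema$required) {
    if (!key %in% names(payload)) {
      abort(sprintf("Report is missing required field '%s'.", key))
    }
  }
  for (key in names(schema$properties)) {
    if (!key %in% names(payload)) next
    type <- schema$properties[[key]]$type
    val <- payload[[key]]
    ok <- switch(type,
      number = is.numeric(val) || is.na(val),
      string = is.character(val),
      object = is.list(val),
      TRUE
    )
    if (!ok) abort(sprintf("Report field '%s' is not of type %s.", key, type))
  }
  invisible(TRUE)
}
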