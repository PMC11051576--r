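#' Place the luminal reference ROI in the ascending aorta
#'
#' The dynamic calcium threshold is derived from a circular ROI covering
#' the central two-thirds of the aortic lumen cross-section, placed 30 mm
#' above the annulus plane along the slice axis. The ROI is concentric
#' with the lumen; covering a fraction `f` of the lumen area means an ROI
#' radius of `lumen_radius * sqrt(f)`.
#'
#' @param volume A contrast-enhanced [ct_volume].
#' @param annulus_slice 1-based slice index of the aortic annulus.
#' @param lumen_center Lumen centre `(row_mm, col_mm)` at the ROI plane.
#' @param lumen_radius Lumen radius, mm.
#' @param offset_mm Distance above the annulus, mm (default 30).
#' @param area_fraction Fraction of the lumen cross-sectional area the ROI
#'   covers (default 2/3).
#' @return An `roi_spec` list: `slice_index`, `center_mm`, `radius_mm`,
#'   `area_fraction`.
#' @examples
#' # a 15 mm lumen gives an ROI radius of 15 * sqrt(2/3) ~ 12.25 mm
#' @export
place_roi <- function(volume, annulus_slice, lumen_center, lumen_radius,
                      offset_mm = 30, area_fraction = 2 / 3) {
  stopifnot(inherits(volume, "ct_volume"))
  if (area_fraction <= 0 || area_fraction > 1) {
    abort("area_fraction must be in (0, 1].")
  }
  slice_index <- annulus_slice + round(offset_mm / volume$slice_increment)
  d <- dim(volume$voxels)
  if (slice_index < 1 || slice_index > d[1]) {
    abort(sprintf(
      "ROI plane %g mm above the annulus (slice %d) lies outside the volume.",
      offset_mm, slice_index
    ))
  }
  radius <- lumen_radius * sqrt(area_fraction)
  if (radius > lumen_radius - volume$pixel_size / 2) {
    warn("ROI touches the lumen boundary; threshold may be contaminated by wall voxels.")
  }
  structure(
    list(slice_index = as.integer(slice_index),
         center_mm = as.numeric(lumen_center),
         radius_mm = radius,
         area_fraction = area_fraction),
    class = "roi_spec"
  )
}

#' Measure luminal attenuation statistics in an ROI
#'
#' Mean and population standard deviation of the HU over voxels whose
#' centres fall inside the ROI disc (population SD is what scanner consoles
#' report for an ROI).
#'
#' @param volume A [ct_volume].
#' @param roi An `roi_spec` from [place_roi].
#' @return An `roi_stats` list: `mean_hu`, `sd_hu`, `n_voxels`.
#' @export
roi_stats <- function(volume, roi) {
  stopifnot(inherits(volume, "ct_volume"), inherits(roi, "roi_spec"))
  d <- dim(volume$voxels)
  if (roi$slice_index < 1 || roi$slice_index > d[1]) {
    abort("ROI slice lies outside the volume.")
  }
  dy2 <- ((seq_len(d[2]) - 1) * volume$pixel_size - roi$center_mm[1])^2
  dx2 <- ((seq_len(d[3]) - 1) * volume$pixel_size - roi$center_mm[2])^2
  disc <- outer(dy2, dx2, "+") <= roi$radius_mm^2
  if (!any(disc)) abort("ROI contains no voxel centres.")
  vals <- array(volume$voxels[roi$slice_index, , ], dim = c(d[2], d[3]))[disc]
  n <- length(vals)
  mu <- mean(vals)
  sigma <- sqrt(sum((vals - mu)^2) / n)  # population SD
  structure(list(mean_hu = mu, sd_hu = sigma, n_voxels = n),
            class = "roi_stats")
}

#' Patient-specific calcium threshold for contrast-enhanced CT
#'
#' `threshold = mean + k * SD` of the luminal ROI attenuation; `k = 4`
#' lifts the cutoff above the contrast-opacified blood pool so only
#' calcium remains suprathreshold.
#'
#' @param stats An `roi_stats` from [roi_stats].
#' @param k SD multiplier (> 0, default 4).
#' @return Threshold in HU.
#' @examples
#' s <- structure(list(mean_hu = 350, sd_hu = 25, n_voxels = 500),
#'                class = "roi_stats")
#' dynamic_threshold(s)  # 450
#' @export
dynamic_threshold <- function(stats, k = 4) {
  stopifnot(inherits(stats, "roi_stats"))
  if (k <= 0) abort("k must be > 0.")
  stats$mean_hu + k * stats$sd_hu
}

#' Segment aortic valve calcium on contrast-enhanced CT
#'
#' Counts voxels at or above the dynamic threshold inside the valve region
#' and outside any exclusion mask, and converts the count to a calcium
#' volume (`count * pixel_size^2 * slice_increment`). This volume
#' (AVC_CECT) is the regressor of the linear conversion to calculated
#' Agatston units.
#'
#' @param volume A contrast-enhanced [ct_volume].
#' @param threshold HU threshold (inclusive), typically from
#'   [dynamic_threshold].
#' @param valve_mask Optional logical mask delimiting the valve region
#'   (replaces the manual selection of clinical workstations). `NULL`
#'   means the whole volume.
#' @param exclusion Optional logical mask of adjacent calcified structures
#'   to remove.
#' @param roi Optional `roi_stats` recorded into the result for provenance.
#' @param verbose Log threshold and voxel count via `message()`.
#' @return A `cect_result`: `threshold`, `volume_mm3`, `voxel_count`,
#'   `roi_stats`.
#' @export
segment_calcium <- function(volume, threshold, valve_mask = NULL,
                            exclusion = NULL, roi = NULL, verbose = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  valve_mask <- check_mask(valve_mask, volume, "Valve region")
  exclusion <- check_mask(exclusion, volume, "Exclusion")
  hot <- volume$voxels >= threshold
  if (!is.null(valve_mask)) hot <- hot & valve_mask
  if (!is.null(exclusion)) hot <- hot & !exclusion
  count <- sum(hot)
  vol <- count * voxel_volume(volume)
  if (verbose) {
    message(sprintf(
      "cect segmentation: threshold %.1f HU, %d voxel(s), volume %.1f mm3",
      threshold, count, vol
    ))
  }
  structure(
    list(threshold = threshold, volume_mm3 = vol, voxel_count = count,
         roi_stats = roi),
    class = "cect_result"
  )
}

#' Quantify valve calcium on a contrast-enhanced volume (full pipeline)
#'
#' Places the luminal ROI 30 mm above the annulus, measures its
#' attenuation, derives the dynamic threshold (mean + k SD), and segments
#' suprathreshold calcium in the valve region.
#'
#' @param volume A contrast-enhanced [ct_volume].
#' @param annulus_slice,lumen_center,lumen_radius ROI placement; see
#'   [place_roi].
#' @param k SD multiplier for the threshold (default 4).
#' @param valve_mask,exclusion Masks passed to [segment_calcium].
#' @param offset_mm,area_fraction ROI geometry; see [place_roi].
#' @param verbose Log per-stage provenance.
#' @return A `cect_result`.
#' @examples
#' ph <- make_cect_phantom(phantom_spec(noise_sd = 0))
#' res <- score_cect(ph$volume, annulus_slice = 10,
#'                   lumen_center = c(31.75, 31.75), lumen_radius = 15)
#' res$volume_mm3
#' @export
score_cect <- function(volume, annulus_slice, lumen_center, lumen_radius,
                       k = 4, valve_mask = NULL, exclusion = NULL,
                       offset_mm = 30, area_fraction = 2 / 3,
                       verbose = FALSE) {
  roi <- place_roi(volume, annulus_slice, lumen_center, lumen_radius,
                   offset_mm = offset_mm, area_fraction = area_fraction)
  stats <- roi_stats(volume, roi)
  thr <- dynamic_threshold(stats, k = k)
  if (verbose) {
    message(sprintf(
      "luminal ROI: slice %d, mean %.1f HU, SD %.1f HU (n = %d) -> threshold %.1f HU",
      roi$slice_index, stats$mean_hu, stats$sd_hu, stats$n_voxels, thr
    ))
  }
  segment_calcium(volume, thr, valve_mask = valve_mask,
                  exclusion = exclusion, roi = stats, verbose = verbose)
}

#' @export
print.cect_result <- function(x, ...) {
  cat(sprintf(
    "<cect_result> threshold %.1f HU, calcium volume %.1f mm3 (%d voxels)\n",
    x$threshold, x$volume_mm3, x$voxel_count
  ))
  if (!is.null(x$roi_stats)) {
    cat(sprintf("  luminal ROI: mean %.1f HU, SD %.1f HU, %d voxels\n",
                x$roi_stats$mean_hu, x$roi_stats$sd_hu, x$roi_stats$n_voxels))
  }
  invisible(x)
}

#' @export
glance.cect_result <- function(x, ...) {
  tibble(
    threshold = x$threshold, volume_mm3 = x$volume_mm3,
    voxel_count = x$voxel_count,
    roi_mean_hu = if (is.null(x$roi_stats)) NA_real_ else x$roi_stats$mean_hu,
    roi_sd_hu = if (is.null(x$roi_stats)) NA_real_ else x$roi_stats$sd_hu
  )
}
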