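#' Resample thin slices into scoring slabs
#'
#' Classic Agatston scoring is defined on 3 mm slices. Modern ECG-gated
#' acquisitions reconstruct much thinner, overlapping slices (here 1 mm
#' every 0.75 mm), so consecutive non-overlapping groups of thin slices are
#' averaged into slabs before lesion detection, approximating a thick-slice
#' reconstruction. In-plane geometry is unchanged; a trailing group of
#' fewer than `slab_thickness / slice_increment` slices is dropped.
#'
#' @param volume A [ct_volume].
#' @param slab_thickness Target slab thickness, mm; must be a whole number
#'   of slice increments (3 mm over a 0.75 mm increment gives 4-slice
#'   slabs), otherwise an error.
#' @return A [ct_volume] whose slices are the slabs.
#' @export
resample_slabs <- function(volume, slab_thickness = 3) {
  stopifnot(inherits(volume, "ct_volume"))
  k <- slab_thickness / volume$slice_increment
  if (abs(k - round(k)) > 1e-9) {
    abort(sprintf(
      "Slab thickness %g mm is not a whole multiple of the %g mm slice increment.",
      slab_thickness, volume$slice_increment
    ))
  }
  k <- as.integer(round(k))
  d <- dim(volume$voxels)
  n_slabs <- d[1] %/% k
  if (n_slabs < 1L) abort("Volume has fewer slices than one slab.")
  v <- volume$voxels[seq_len(n_slabs * k), , , drop = FALSE]
  dim(v) <- c(k, n_slabs, d[2], d[3])
  slabs <- colMeans(v)  # average over the k constituent thin slices
  ct_volume(slabs, volume$pixel_size,
    slice_increment = slab_thickness, slice_thickness = slab_thickness,
    tube_voltage = volume$tube_voltage, modality = volume$modality
  )
}

#' Agatston density weight
#'
#' Maps a lesion's maximum attenuation to the classic density factor:
#' 130-199 HU -> 1, 200-299 -> 2, 300-399 -> 3, >= 400 -> 4. Values below
#' 130 HU cannot belong to a lesion and raise an error.
#'
#' @param max_hu Numeric vector of per-lesion maximum HU.
#' @return Integer weights in 1..4.
#' @examples
#' density_weight(c(130, 199, 200, 399, 400, 1200))
#' @export
density_weight <- function(max_hu) {
  if (any(max_hu < 130)) {
    abort("Density weight is undefined below 130 HU (no lesion can exist there).")
  }
  as.integer(cut(max_hu, breaks = c(130, 200, 300, 400, Inf),
                 right = FALSE, labels = FALSE))
}

#' Detect calcified lesions on scoring slabs
#'
#' Finds per-slab connected components of voxels at or above the threshold
#' (8-connectivity in plane by default, as in slice-wise Agatston scoring;
#' a 3D 26-connected mode is available), discards components smaller than
#' `min_area`, and annotates each lesion with its area, maximum HU and
#' density weight.
#'
#' @param slabs A [ct_volume], typically from [resample_slabs].
#' @param threshold Detection threshold in HU, inclusive (default 130).
#' @param min_area Minimum lesion area in mm^2 (default 1; components with
#'   area >= 1 mm^2 are kept).
#' @param mode `"2d"` (per-slab components, classic) or `"3d"`.
#' @return Tibble with one row per lesion: `lesion_id`, `slab`,
#'   `pixel_count`, `area_mm2`, `max_hu`, `weight`, `score` (area x weight).
#'   In 3D mode `slab` is the component's first slab and `area_mm2` the
#'   component's total in-plane area.
#' @export
detect_lesions <- function(slabs, threshold = 130, min_area = 1,
                           mode = c("2d", "3d")) {
  stopifnot(inherits(slabs, "ct_volume"))
  mode <- match.arg(mode)
  px2 <- slabs$pixel_size^2
  vox <- slabs$voxels
  d <- dim(vox)
  rows <- list()
  if (mode == "2d") {
    for (s in seq_len(d[1])) {
      slab <- array(vox[s, , ], dim = c(d[2], d[3]))
      mask <- slab >= threshold
      if (!any(mask)) next
      lab <- label_components(mask)
      for (comp in split(which(mask), lab)) {
        area <- length(comp) * px2
        if (area < min_area - 1e-12) next
        maxhu <- max(slab[comp])
        rows[[length(rows) + 1]] <- tibble(
          slab = s, pixel_count = length(comp), area_mm2 = area, max_hu = maxhu
        )
      }
    }
  } else {
    mask <- vox >= threshold
    if (any(mask)) {
      lab <- label_components(mask)
      for (comp in split(which(mask), lab)) {
        area <- length(comp) * px2
        if (area < min_area - 1e-12) next
        first_slab <- min(arrayInd(comp, d)[, 1])
        rows[[length(rows) + 1]] <- tibble(
          slab = first_slab, pixel_count = length(comp),
          area_mm2 = area, max_hu = max(vox[comp])
        )
      }
    }
  }
  if (!length(rows)) {
    return(tibble(lesion_id = integer(), slab = integer(),
                  pixel_count = integer(), area_mm2 = numeric(),
                  max_hu = numeric(), weight = integer(), score = numeric()))
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    lesion_id = dplyr::row_number(),
    weight = density_weight(.data$max_hu),
    score = .data$area_mm2 * .data$weight
  )
  dplyr::select(out, "lesion_id", "slab", "pixel_count", "area_mm2",
                "max_hu", "weight", "score")
}

# connected-component labelling of a logical 2D matrix (8-connectivity) or
# 3D array (26-connectivity), via an adjacency graph over foreground voxels
label_components <- function(mask) {
  dims <- dim(mask)
  nd <- length(dims)
  ids <- which(mask)
  vid <- array(0L, dim = dims)
  vid[ids] <- seq_along(ids)
  offsets <- if (nd == 2L) {
    list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  } else {
    # forward half of the 26-neighbourhood: lexicographically positive
    # offsets only, so each neighbour pair is visited once
    o <- as.matrix(expand.grid(ds = -1:1, dr = -1:1, dc = -1:1))
    keep <- apply(o, 1, function(v) {
      nz <- which(v != 0)
      length(nz) > 0 && v[nz[1]] > 0
    })
    lapply(which(keep), function(i) as.integer(o[i, ]))
  }
  coords <- arrayInd(ids, dims)
  strides <- c(1, cumprod(dims)[-nd])
  edges <- list()
  for (off in offsets) {
    nb <- sweep(coords, 2L, off, "+")
    ok <- rep(TRUE, nrow(nb))
    for (ax in seq_len(nd)) ok <- ok & nb[, ax] >= 1L & nb[, ax] <= dims[ax]
    if (!any(ok)) next
    lin <- as.integer(1 + (nb[ok, , drop = FALSE] - 1) %*% strides)
    src <- vid[ids[ok]]
    dst <- vid[lin]
    hit <- dst > 0L
    if (any(hit)) edges[[length(edges) + 1]] <- cbind(src[hit], dst[hit])
  }
  e <- if (length(edges)) do.call(rbind, edges) else matrix(integer(), ncol = 2)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  if (nrow(e)) g <- igraph::add_edges(g, as.vector(t(e)))
  membership <- igraph::components(g)$membership
  lab <- array(0L, dim = dims)
  lab[ids] <- as.integer(membership)
  lab[ids]
}

#' Total an Agatston score from detected lesions
#'
#' Sums per-lesion contributions (area x density weight) and measures the
#' suprathreshold calcium volume on the un-slabbed thin-slice volume, using
#' the slice increment as the through-plane voxel dimension.
#'
#' @param lesions Lesion tibble from [detect_lesions].
#' @param volume The thin-slice [ct_volume] the lesions came from (after
#'   any exclusion), used for the volume measurement.
#' @param threshold HU threshold for the volume measurement (default 130).
#' @return An `agatston_result`: total score, calcium volume mm^3, the
#'   lesion table, and the threshold/slab settings used.
#' @export
agatston_score <- function(lesions, volume, threshold = 130) {
  stopifnot(inherits(volume, "ct_volume"))
  total <- sum(lesions$score)
  vol_mm3 <- sum(volume$voxels >= threshold) * voxel_volume(volume)
  structure(
    list(
      total = total,
      volume_mm3 = vol_mm3,
      lesions = lesions,
      threshold = threshold,
      slab_thickness = NA_real_
    ),
    class = "agatston_result"
  )
}

#' Score a native CT volume (full pipeline)
#'
#' Applies the optional manual-exclusion mask, averages thin slices into
#' scoring slabs, detects lesions at the (inclusive) HU threshold, and
#' totals the Agatston score. This is the reference-standard measurement
#' that contrast-enhanced quantification is calibrated against.
#'
#' @param volume A native [ct_volume].
#' @param exclusion Optional logical mask of adjacent calcified structures
#'   (coronaries, aortic wall) to remove before scoring.
#' @param threshold Detection threshold, HU (default 130, the standard
#'   calcium cutoff at 120 kV).
#' @param slab_thickness Scoring slab thickness, mm (default 3).
#' @param min_area Minimum lesion area, mm^2 (default 1).
#' @param mode Connectivity mode passed to [detect_lesions].
#' @param verbose Log the threshold and lesion count via `message()`.
#' @return An `agatston_result`.
#' @examples
#' ph <- make_native_phantom(phantom_spec(noise_sd = 0))
#' res <- score_native(ph$volume)
#' res$total
#' @export
score_native <- function(volume, exclusion = NULL, threshold = 130,
                         slab_thickness = 3, min_area = 1,
                         mode = c("2d", "3d"), verbose = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  mode <- match.arg(mode)
  exclusion <- check_mask(exclusion, volume, "Exclusion")
  vol <- apply_exclusion(volume, exclusion)
  slabs <- resample_slabs(vol, slab_thickness)
  lesions <- detect_lesions(slabs, threshold = threshold,
                            min_area = min_area, mode = mode)
  res <- agatston_score(lesions, vol, threshold = threshold)
  res$slab_thickness <- slab_thickness
  if (verbose) {
    message(sprintf(
      "native scoring: threshold %g HU, %d lesion(s), score %.1f, volume %.1f mm3",
      threshold, nrow(lesions), res$total, res$volume_mm3
    ))
  }
  res
}

#' @export
print.agatston_result <- function(x, ...) {
  cat(sprintf("<agatston_result> score %.1f AU, calcium volume %.1f mm3\n",
              x$total, x$volume_mm3))
  cat(sprintf("  %d lesion(s), threshold %g HU, slab %s mm\n",
              nrow(x$lesions), x$threshold,
              ifelse(is.na(x$slab_thickness), "?", format(x$slab_thickness))))
  invisible(x)
}

#' @export
tidy.agatston_result <- function(x, ...) x$lesions

#' @export
glance.agatston_result <- function(x, ...) {
  tibble(total = x$total, volume_mm3 = x$volume_mm3,
         n_lesions = nrow(x$lesions), threshold = x$threshold,
         slab_thickness = x$slab_thickness)
}
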