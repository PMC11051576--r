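#' Specify a synthetic aortic-valve CT phantom
#'
#' Describes a paired native / contrast-enhanced phantom: a cylindrical
#' ascending-aorta lumen running along the slice axis, spherical calcific
#' lesions at the valve plane, optional distractor calcifications (coronary
#' or aortic-wall), and per-voxel Gaussian noise. The same geometry renders
#' as a native scan (blood-pool attenuation in the lumen) or a
#' contrast-enhanced scan (opacified lumen), so ground truth is shared.
#'
#' Geometry defaults mirror a TAVI planning acquisition: 1 mm slices
#' reconstructed every 0.75 mm, sub-millimetre in-plane pixels, and the
#' annulus placed so that a 30 mm offset up the ascending aorta stays
#' inside the grid. Default lumen enhancement (360 HU) and noise (25 HU)
#' give dynamic thresholds (mean + 4 SD = 460 HU) in the range reported
#' for clinical TAVI cohorts; neither is a measured scanner property.
#'
#' Coordinates are physical mm with the first voxel centre at the origin:
#' a lesion centre is `(z_mm, row_mm, col_mm)` with
#' `z = (slice - 1) * slice_increment`.
#'
#' @param grid_shape Integer vector (slices, rows, cols).
#' @param pixel_size In-plane pixel edge, mm.
#' @param slice_increment Slice spacing, mm.
#' @param slice_thickness Reconstructed slice thickness, mm.
#' @param lumen List with `center_mm` (row, col), `radius_mm`,
#'   `enhancement_hu` (contrast-enhanced luminal mean) and
#'   `native_blood_hu`.
#' @param background_hu Attenuation outside the lumen.
#' @param lesions Tibble/data frame of valve lesions with columns
#'   `z_mm`, `row_mm`, `col_mm`, `radius_mm`, `peak_hu`.
#' @param distractors Same shape as `lesions`; calcifications outside the
#'   valve region (rendered, but never part of the valve ground truth).
#' @param noise_sd Per-voxel Gaussian noise SD, HU.
#' @param annulus_slice_index 1-based slice index of the aortic annulus.
#' @param smooth_sd_mm Optional Gaussian partial-volume blur applied to the
#'   noiseless rendering (0 = off; keeps the analytic truth exact).
#' @param seed Integer seed; mandatory for any `noise_sd > 0`.
#'
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(60L, 128L, 128L),
                         pixel_size = 0.5,
                         slice_increment = 0.75,
                         slice_thickness = 1,
                         lumen = list(center_mm = c(31.75, 31.75),
                                      radius_mm = 15,
                                      enhancement_hu = 360,
                                      native_blood_hu = 40),
                         background_hu = -50,
                         lesions = tibble(
                           z_mm = 6.75, row_mm = 31.75, col_mm = 31.75,
                           radius_mm = 4, peak_hu = 800
                         ),
                         distractors = NULL,
                         noise_sd = 25,
                         annulus_slice_index = 10L,
                         smooth_sd_mm = 0,
                         seed = 1L) {
  lesions <- if (is.null(lesions)) empty_lesion_table() else as_tibble(lesions)
  distractors <- if (is.null(distractors)) empty_lesion_table() else as_tibble(distractors)
  spec <- structure(
    list(
      grid_shape = as.integer(grid_shape),
      pixel_size = pixel_size,
      slice_increment = slice_increment,
      slice_thickness = slice_thickness,
      lumen = lumen,
      background_hu = background_hu,
      lesions = lesions,
      distractors = distractors,
      noise_sd = noise_sd,
      annulus_slice_index = as.integer(annulus_slice_index),
      smooth_sd_mm = smooth_sd_mm,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

empty_lesion_table <- function() {
  tibble(z_mm = numeric(), row_mm = numeric(), col_mm = numeric(),
         radius_mm = numeric(), peak_hu = numeric())
}

validate_phantom_spec <- function(spec) {
  g <- spec$grid_shape
  if (length(g) != 3L || any(g < 1L)) abort("grid_shape must be 3 positive integers.")
  if (spec$pixel_size <= 0 || spec$slice_increment <= 0) {
    abort("pixel_size and slice_increment must be positive.")
  }
  if (spec$slice_thickness < spec$slice_increment) {
    abort("slice_thickness must be >= slice_increment.")
  }
  if (spec$noise_sd < 0) abort("noise_sd must be >= 0.")
  if (spec$lumen$radius_mm <= 0) abort("Lumen radius must be positive.")
  les <- spec$lesions
  if (nrow(les) && any(les$radius_mm <= 0)) abort("Lesion radii must be positive.")
  if (nrow(les) && any(les$peak_hu <= spec$background_hu)) {
    abort("Lesion peak HU must exceed the background attenuation.")
  }
  extent <- c((g[1] - 1) * spec$slice_increment,
              (g[2] - 1) * spec$pixel_size,
              (g[3] - 1) * spec$pixel_size)
  check_inside <- function(tab, what) {
    if (!nrow(tab)) return(invisible())
    ctr <- cbind(tab$z_mm, tab$row_mm, tab$col_mm)
    for (ax in 1:3) {
      if (any(ctr[, ax] - tab$radius_mm < 0) ||
          any(ctr[, ax] + tab$radius_mm > extent[ax])) {
        abort(sprintf("%s extend outside the phantom grid.", what))
      }
    }
  }
  check_inside(les, "Lesions")
  check_inside(spec$distractors, "Distractors")
  # the ROI plane 30 mm above the annulus must exist
  roi_slice <- spec$annulus_slice_index + round(30 / spec$slice_increment)
  if (spec$annulus_slice_index < 1L || roi_slice > g[1]) {
    abort("Grid too short: the plane 30 mm above the annulus falls outside it.")
  }
  invisible(spec)
}

# squared-distance field from a physical point; voxel-centre membership
sphere_mask <- function(spec, center_mm, radius_mm) {
  g <- spec$grid_shape
  dz2 <- ((seq_len(g[1]) - 1) * spec$slice_increment - center_mm[1])^2
  dy2 <- ((seq_len(g[2]) - 1) * spec$pixel_size - center_mm[2])^2
  dx2 <- ((seq_len(g[3]) - 1) * spec$pixel_size - center_mm[3])^2
  outer(outer(dz2, dy2, "+"), dx2, "+") <= radius_mm^2
}

lumen_mask <- function(spec) {
  g <- spec$grid_shape
  dy2 <- ((seq_len(g[2]) - 1) * spec$pixel_size - spec$lumen$center_mm[1])^2
  dx2 <- ((seq_len(g[3]) - 1) * spec$pixel_size - spec$lumen$center_mm[2])^2
  disc <- outer(dy2, dx2, "+") <= spec$lumen$radius_mm^2
  aperm(array(disc, dim = c(g[2], g[3], g[1])), c(3, 1, 2))
}

lesion_union_mask <- function(spec, tab) {
  m <- array(FALSE, dim = spec$grid_shape)
  if (!nrow(tab)) return(m)
  for (i in seq_len(nrow(tab))) {
    m <- m | sphere_mask(spec, c(tab$z_mm[i], tab$row_mm[i], tab$col_mm[i]),
                         tab$radius_mm[i])
  }
  m
}

# noiseless rendering shared by the native and contrast phantoms
render_phantom <- function(spec, lumen_hu) {
  vox <- array(spec$background_hu, dim = spec$grid_shape)
  vox[lumen_mask(spec)] <- lumen_hu
  paint <- function(vox, tab) {
    for (i in seq_len(nrow(tab))) {
      m <- sphere_mask(spec, c(tab$z_mm[i], tab$row_mm[i], tab$col_mm[i]),
                       tab$radius_mm[i])
      vox[m] <- pmax(vox[m], tab$peak_hu[i])
    }
    vox
  }
  vox <- paint(vox, spec$lesions)
  vox <- paint(vox, spec$distractors)
  if (spec$smooth_sd_mm > 0) vox <- gaussian_blur3d(vox, spec, spec$smooth_sd_mm)
  vox
}

# separable Gaussian blur, reflective edges; sigma in mm
gaussian_blur3d <- function(vox, spec, sigma_mm) {
  blur_axis <- function(a, axis, spacing) {
    sigma <- sigma_mm / spacing
    half <- max(1L, ceiling(3 * sigma))
    k <- exp(-0.5 * ((-half:half) / sigma)^2)
    k <- k / sum(k)
    n <- dim(a)[axis]
    idx <- function(i) pmin(pmax(i, 1L), n)  # clamp (replicate) padding
    out <- array(0, dim = dim(a))
    for (o in -half:half) {
      sl <- idx(seq_len(n) + o)
      take <- switch(axis, a[sl, , , drop = FALSE], a[, sl, , drop = FALSE],
                     a[, , sl, drop = FALSE])
      out <- out + k[o + half + 1] * take
    }
    out
  }
  vox <- blur_axis(vox, 1L, spec$slice_increment)
  vox <- blur_axis(vox, 2L, spec$pixel_size)
  blur_axis(vox, 3L, spec$pixel_size)
}

add_noise <- function(vox, spec) {
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vox <- vox + array(rnorm(length(vox), 0, spec$noise_sd), dim = dim(vox))
  }
  vox
}

finish_truth <- function(spec, calcium_mask, distractor_mask, noiseless_native) {
  if (any(calcium_mask & distractor_mask)) {
    abort("Distractors overlap valve lesions; ground truth would be ambiguous.")
  }
  voxvol <- spec$pixel_size^2 * spec$slice_increment
  true_volume <- sum(calcium_mask) * voxvol
  stopifnot(isTRUE(all.equal(true_volume, sum(calcium_mask) * voxvol)))
  # reference score on the noiseless native rendering, distractors excluded
  vol <- ct_volume(noiseless_native, spec$pixel_size, spec$slice_increment,
                   spec$slice_thickness, 120, "native")
  ref <- reference_agatston(vol, exclusion = distractor_mask)
  list(
    calcium_mask = calcium_mask,
    distractor_mask = distractor_mask,
    true_volume_mm3 = true_volume,
    true_agatston = ref$total,
    lesions = spec$lesions
  )
}

#' Generate a native (non-contrast) phantom scan
#'
#' Renders the phantom with blood-pool attenuation in the lumen, adds
#' seeded Gaussian noise, and returns the volume together with its ground
#' truth: the mask of noiseless valve-lesion voxels at >= 130 HU, their
#' volume, and the Agatston score computed by the brute-force reference
#' scorer ([reference_agatston]) with distractors excluded.
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `volume` ([ct_volume], modality native,
#'   120 kV) and `truth` (calcium mask, distractor mask, true volume mm^3,
#'   true Agatston score, lesion table).
#' @export
make_native_phantom <- function(spec) {
  validate_phantom_spec(spec)
  noiseless <- render_phantom(spec, spec$lumen$native_blood_hu)
  lesion_m <- lesion_union_mask(spec, spec$lesions)
  distract_m <- lesion_union_mask(spec, spec$distractors)
  calcium <- lesion_m & (noiseless >= 130)
  truth <- finish_truth(spec, calcium, distract_m, noiseless)
  vox <- add_noise(noiseless, spec)
  list(
    volume = ct_volume(vox, spec$pixel_size, spec$slice_increment,
                       spec$slice_thickness, 120, "native"),
    truth = truth
  )
}

#' Generate a contrast-enhanced phantom scan
#'
#' Same geometry as [make_native_phantom] but with the lumen opacified at
#' `lumen$enhancement_hu`. The ground-truth calcium mask holds the
#' noiseless valve-lesion voxels strictly above the dynamic threshold
#' `enhancement_hu + 4 * noise_sd`, i.e. the voxels a correctly derived
#' patient-specific threshold should segment.
#'
#' @param spec A [phantom_spec] (with `lumen$enhancement_hu` set).
#' @return A list with `volume` (modality contrast, 100 kV) and `truth`;
#'   `truth$true_agatston` still refers to the paired native rendering.
#' @export
make_cect_phantom <- function(spec) {
  validate_phantom_spec(spec)
  if (is.null(spec$lumen$enhancement_hu)) abort("lumen$enhancement_hu must be set.")
  noiseless_cect <- render_phantom(spec, spec$lumen$enhancement_hu)
  noiseless_native <- render_phantom(spec, spec$lumen$native_blood_hu)
  lesion_m <- lesion_union_mask(spec, spec$lesions)
  distract_m <- lesion_union_mask(spec, spec$distractors)
  thr <- spec$lumen$enhancement_hu + 4 * spec$noise_sd
  calcium <- lesion_m & (noiseless_cect > thr)
  truth <- finish_truth(spec, calcium, distract_m, noiseless_native)
  vox <- add_noise(noiseless_cect, spec)
  list(
    volume = ct_volume(vox, spec$pixel_size, spec$slice_increment,
                       spec$slice_thickness, 100, "contrast"),
    truth = truth
  )
}

#' Brute-force reference Agatston scorer
#'
#' An independently coded per-voxel scorer kept deliberately simple —
#' explicit slab averaging, stack-based 8-connected flood fill per slab,
#' inline density brackets — for validating the production scorer
#' ([score_native]) and for phantom ground truth. Not optimised; intended
#' for small volumes.
#'
#' @param volume A native-modality [ct_volume].
#' @param exclusion Optional logical mask of voxels to remove first.
#' @param threshold HU threshold (inclusive), default 130.
#' @param slab_thickness Scoring slab thickness, mm (default 3).
#' @param min_area Minimum lesion area, mm^2 (default 1).
#' @return List with `total` (Agatston units) and `volume_mm3` (suprathreshold
#'   voxel volume of the un-slabbed grid).
#' @export
reference_agatston <- function(volume, exclusion = NULL, threshold = 130,
                               slab_thickness = 3, min_area = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  vox <- volume$voxels
  if (!is.null(exclusion)) vox[as.logical(exclusion)] <- -1024
  px <- volume$pixel_size
  k <- slab_thickness / volume$slice_increment
  if (abs(k - round(k)) > 1e-9) {
    abort("Slab thickness is not a whole number of slice increments.")
  }
  k <- round(k)
  d <- dim(vox)
  n_slabs <- d[1] %/% k
  total <- 0
  for (s in seq_len(n_slabs)) {
    slab <- matrix(0, d[2], d[3])
    for (j in seq_len(k)) slab <- slab + vox[(s - 1) * k + j, , ]
    slab <- slab / k
    hot <- slab >= threshold
    seen <- matrix(FALSE, d[2], d[3])
    for (lin in which(hot)) {
      r0 <- ((lin - 1) %% d[2]) + 1
      c0 <- ((lin - 1) %/% d[2]) + 1
      {
        if (seen[r0, c0]) next
        stack <- list(c(r0, c0))
        seen[r0, c0] <- TRUE
        pix <- list()
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          pix[[length(pix) + 1]] <- p
          for (dr in -1:1) for (dc in -1:1) {
            rr <- p[1] + dr; cc <- p[2] + dc
            if (rr < 1 || cc < 1 || rr > d[2] || cc > d[3]) next
            if (hot[rr, cc] && !seen[rr, cc]) {
              seen[rr, cc] <- TRUE
              stack[[length(stack) + 1]] <- c(rr, cc)
            }
          }
        }
        area <- length(pix) * px^2
        if (area < min_area - 1e-12) next
        maxhu <- max(vapply(pix, function(p) slab[p[1], p[2]], numeric(1)))
        w <- if (maxhu >= 400) 4 else if (maxhu >= 300) 3 else
             if (maxhu >= 200) 2 else 1
        total <- total + area * w
      }
    }
  }
  list(total = total,
       volume_mm3 = sum(vox >= threshold) * px^2 * volume$slice_increment)
}

#' Simulate a paired native/CECT measurement cohort
#'
#' Draws contrast-enhanced calcium volumes uniformly from `volume_range`
#' and generates paired native Agatston scores from a linear conversion
#' relation plus Gaussian measurement noise. Used to study calibration
#' recovery and agreement statistics under known truth. Defaults mirror a
#' TAVI derivation cohort: n = 45 subjects with calcium volumes spanning
#' roughly 300-2500 mm^3 and score noise of 400 Agatston units.
#'
#' @param n Number of subjects (>= 3).
#' @param model A [conversion_model] acting as the generating relation.
#' @param volume_range Length-2 range of CECT calcium volumes, mm^3.
#' @param noise_sd SD of additive Gaussian noise on the native score,
#'   Agatston units.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `cect_volume_mm3`, `native_agatston`.
#' @export
make_paired_cohort <- function(n = 45, model = default_conversion_model(),
                               volume_range = c(300, 2500), noise_sd = 400,
                               seed = 1L) {
  if (n < 3) abort("Need n >= 3 subjects (regression underdetermined below that).")
  if (noise_sd < 0) abort("noise_sd must be >= 0.")
  stopifnot(inherits(model, "conversion_model"))
  set.seed(as.integer(seed))
  v <- runif(n, volume_range[1], volume_range[2])
  y <- model$intercept + model$slope * v + rnorm(n, 0, noise_sd)
  tibble(id = sprintf("S%03d", seq_len(n)),
         cect_volume_mm3 = v, native_agatston = y)
}

#' Simulate a two-method agreement cohort with known population ICC
#'
#' Generates paired measurements `a_i = s_i + e_i1`, `b_i = s_i + e_i2`
#' with between-subject SD `between_sd` and error variance solved from the
#' target intraclass correlation `icc = var_s / (var_s + var_e)` (no
#' systematic method effect). Used to check that the ICC estimator recovers
#' a known population value.
#'
#' @param n Number of subjects.
#' @param icc Target population ICC in (0, 1).
#' @param between_sd Between-subject SD.
#' @param center Grand mean of the measurements.
#' @param seed Integer seed.
#' @return Tibble with columns `id`, `a`, `b`.
#' @export
make_agreement_cohort <- function(n = 20, icc = 0.915, between_sd = 1,
                                  center = 0, seed = 1L) {
  if (icc <= 0 || icc >= 1) abort("Target ICC must lie strictly in (0, 1).")
  set.seed(as.integer(seed))
  sigma_e <- between_sd * sqrt((1 - icc) / icc)
  s <- rnorm(n, 0, between_sd)
  tibble(id = sprintf("S%03d", seq_len(n)),
         a = center + s + rnorm(n, 0, sigma_e),
         b = center + s + rnorm(n, 0, sigma_e))
}
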