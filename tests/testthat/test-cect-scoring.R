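test_that("ROI placement follows the two-thirds-area geometry", {
  sp <- phantom_spec(noise_sd = 0)
  vol <- make_cect_phantom(sp)$volume
  roi <- place_roi(vol, annulus_slice = 10, lumen_center = c(31.75, 31.75),
                   lumen_radius = 15)
  # radius = 15 * sqrt(2/3) ~ 12.247 mm
  expect_equal(roi$radius_mm, 15 * sqrt(2 / 3), tolerance = 1e-12)
  # 30 mm over a 0.75 mm increment: 40 slices above the annulus
  expect_equal(roi$slice_index, 10L + 40L)
  # the discretized ROI area is within 5% of two-thirds of the lumen area
  st <- roi_stats(vol, roi)
  lumen_px <- sum(outer(((seq_len(128) - 1) * 0.5 - 31.75)^2,
                        ((seq_len(128) - 1) * 0.5 - 31.75)^2, "+") <= 15^2)
  expect_lt(abs(st$n_voxels / lumen_px - 2 / 3), 0.05 * 2 / 3)
  # fraction 1 reproduces the lumen radius (and warns: wall contamination)
  expect_warning(
    roi_full <- place_roi(vol, 10, c(31.75, 31.75), 15, area_fraction = 1),
    "lumen boundary"
  )
  expect_equal(roi_full$radius_mm, 15)
  # an offset beyond the grid is refused
  expect_error(place_roi(vol, 30, c(31.75, 31.75), 15), "outside")
})

test_that("ROI statistics are the mean and population SD over the disc", {
  # homogeneous lumen, no noise
  sp <- phantom_spec(noise_sd = 0,
                     lumen = list(center_mm = c(31.75, 31.75), radius_mm = 15,
                                  enhancement_hu = 350, native_blood_hu = 40))
  vol <- make_cect_phantom(sp)$volume
  roi <- place_roi(vol, 10, c(31.75, 31.75), 15)
  st <- roi_stats(vol, roi)
  expect_equal(st$mean_hu, 350)
  expect_equal(st$sd_hu, 0)
  # two-valued ROI {300, 400} in equal halves: mean 350, population SD 50
  vox <- array(300, c(4, 8, 8))
  vox[, , 5:8] <- 400
  flat <- ct_volume(vox, 1, 1, modality = "contrast")
  full <- structure(list(slice_index = 2L, center_mm = c(3.5, 3.5),
                         radius_mm = 10, area_fraction = 1),
                    class = "roi_spec")
  st2 <- roi_stats(flat, full)
  expect_equal(st2$n_voxels, 64L)
  expect_equal(st2$mean_hu, 350)
  expect_equal(st2$sd_hu, 50)
  # noisy phantom: sample SD approaches the generating noise over a large ROI
  spn <- phantom_spec(noise_sd = 25, seed = 8L)
  voln <- make_cect_phantom(spn)$volume
  stn <- roi_stats(voln, place_roi(voln, 10, c(31.75, 31.75), 15))
  expect_lt(abs(stn$sd_hu - 25) / 25, 0.1)
})

test_that("the dynamic threshold is exactly mean + k * SD", {
  st <- structure(list(mean_hu = 400, sd_hu = 20, n_voxels = 100),
                  class = "roi_stats")
  expect_identical(dynamic_threshold(st, k = 4), 480)
  expect_identical(dynamic_threshold(st, k = 2.5), 450)
  st0 <- structure(list(mean_hu = 365.25, sd_hu = 0, n_voxels = 10),
                   class = "roi_stats")
  expect_identical(dynamic_threshold(st0), 365.25)
  expect_error(dynamic_threshold(st, k = 0), "k must be")
})

test_that("noise-free segmentation at the nominal threshold recovers truth exactly", {
  # enhancement 350 HU, nominal noise 25 HU -> threshold 450; an 800 HU
  # lesion clears the margin and every truth voxel, and only those voxels,
  # is suprathreshold in the noise-free rendering
  for (seed in c(4, 9, 31)) {
    set.seed(seed)
    lesions <- tibble::tibble(
      z_mm = runif(2, 4, 28), row_mm = runif(2, 4, 7.5),
      col_mm = runif(2, 4, 7.5), radius_mm = runif(2, 1, 2.5),
      peak_hu = 800
    )
    sp <- phantom_spec(
      grid_shape = c(44L, 24L, 24L), pixel_size = 0.5,
      slice_increment = 0.75, slice_thickness = 1,
      lumen = list(center_mm = c(5.75, 5.75), radius_mm = 3,
                   enhancement_hu = 350, native_blood_hu = 40),
      lesions = lesions, noise_sd = 25, annulus_slice_index = 2L, seed = seed
    )
    truth <- make_cect_phantom(sp)$truth  # truth threshold: 350 + 4*25 = 450
    sp0 <- sp
    sp0$noise_sd <- 0
    ph0 <- make_cect_phantom(sp0)
    seg <- segment_calcium(ph0$volume, 450)
    expect_equal(seg$volume_mm3, truth$true_volume_mm3,
                 info = sprintf("seed %d", seed))
  }
})

test_that("segmented volume is non-increasing in the threshold", {
  sp <- phantom_spec(noise_sd = 25, seed = 12L)
  vol <- make_cect_phantom(sp)$volume
  sweep <- vapply(seq(300, 900, by = 50), function(th) {
    segment_calcium(vol, th)$volume_mm3
  }, numeric(1))
  expect_true(all(diff(sweep) <= 0))
  # a threshold above the global maximum finds nothing
  expect_equal(segment_calcium(vol, max(vol$voxels) + 1)$volume_mm3, 0)
})

test_that("valve and exclusion masks restrict the segmentation", {
  sp <- phantom_spec(
    distractors = tibble::tibble(z_mm = 30, row_mm = 55, col_mm = 55,
                                 radius_mm = 3, peak_hu = 900),
    noise_sd = 0
  )
  ph <- make_cect_phantom(sp)
  thr <- 460
  all_in <- segment_calcium(ph$volume, thr)
  no_distr <- segment_calcium(ph$volume, thr, exclusion = ph$truth$distractor_mask)
  expect_lt(no_distr$volume_mm3, all_in$volume_mm3)
  expect_equal(no_distr$volume_mm3, ph$truth$true_volume_mm3)
  # valve mask: keep only the lesion region
  valve <- ph$truth$calcium_mask
  only_valve <- segment_calcium(ph$volume, thr, valve_mask = valve)
  expect_equal(only_valve$volume_mm3, ph$truth$true_volume_mm3)
  expect_error(segment_calcium(ph$volume, thr, valve_mask = array(TRUE, c(2, 2, 2))),
               "shape")
})

test_that("full CECT pipeline recovers true volume within 10% under noise", {
  errs <- vapply(1:20, function(seed) {
    sp <- phantom_spec(noise_sd = 25, seed = seed)
    ph <- make_cect_phantom(sp)
    res <- score_cect(ph$volume, annulus_slice = 10,
                      lumen_center = c(31.75, 31.75), lumen_radius = 15)
    abs(res$volume_mm3 - ph$truth$true_volume_mm3) / ph$truth$true_volume_mm3
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
})

test_that("per-subject thresholds vary with lumen enhancement and noise", {
  thrs <- vapply(1:8, function(seed) {
    set.seed(seed + 500)
    enh <- runif(1, 300, 450)
    sp <- phantom_spec(
      lumen = list(center_mm = c(31.75, 31.75), radius_mm = 15,
                   enhancement_hu = enh, native_blood_hu = 40),
      noise_sd = 25, seed = seed
    )
    vol <- make_cect_phantom(sp)$volume
    score_cect(vol, 10, c(31.75, 31.75), 15)$threshold
  }, numeric(1))
  expect_gt(sd(thrs), 10)   # patient-specific, not a constant
  expect_true(all(thrs > 300))
})
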