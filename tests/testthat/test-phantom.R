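test_that("a lesion-free noise-free phantom has zero calcium", {
  sp <- phantom_spec(lesions = NULL, noise_sd = 0)
  ph <- make_native_phantom(sp)
  expect_equal(ph$truth$true_volume_mm3, 0)
  expect_equal(ph$truth$true_agatston, 0)
  expect_equal(sum(ph$truth$calcium_mask), 0)
})

test_that("phantom generation is deterministic under a fixed seed", {
  sp <- phantom_spec(noise_sd = 30, seed = 99L)
  a <- make_native_phantom(sp)
  b <- make_native_phantom(sp)
  expect_identical(a$volume$voxels, b$volume$voxels)
  c1 <- make_cect_phantom(sp)
  c2 <- make_cect_phantom(sp)
  expect_identical(c1$volume$voxels, c2$volume$voxels)
  # different seed, different noise
  sp2 <- phantom_spec(noise_sd = 30, seed = 100L)
  expect_false(identical(a$volume$voxels, make_native_phantom(sp2)$volume$voxels))
})

test_that("a single-slab 10-pixel 450 HU lesion scores exactly 10 Agatston units", {
  # 10 pixels of 0.25 mm^2 at 450 HU: area 2.5 mm^2, density weight 4
  slice <- matrix(0, 16, 16)
  slice[5, 4:8] <- 450
  slice[6, 4:8] <- 450
  vol <- block_volume(slice, pixel_size = 0.5)
  res <- score_native(vol)
  expect_equal(nrow(res$lesions), 1L)
  expect_equal(res$lesions$area_mm2, 2.5)
  expect_equal(res$lesions$weight, 4L)
  expect_equal(res$total, 10)
  # the brute-force reference agrees
  expect_equal(reference_agatston(vol)$total, 10)
})

test_that("truth volume equals suprathreshold voxel count times voxel volume", {
  for (seed in c(3, 17, 41)) {
    sp <- random_small_spec(seed, noise_sd = 0)
    ph <- make_native_phantom(sp)
    voxvol <- sp$pixel_size^2 * sp$slice_increment
    expect_equal(ph$truth$true_volume_mm3, sum(ph$truth$calcium_mask) * voxvol)
    ce <- make_cect_phantom(sp)
    expect_equal(ce$truth$true_volume_mm3, sum(ce$truth$calcium_mask) * voxvol)
  }
})

test_that("noise-free phantom voxels take their analytic geometry values", {
  sp <- phantom_spec(noise_sd = 0)
  ph <- make_cect_phantom(sp)
  vox <- ph$volume$voxels
  expect_setequal(unique(as.vector(vox)),
                  c(sp$background_hu, sp$lumen$enhancement_hu,
                    sp$lesions$peak_hu))
  # lesion centre voxel carries the peak
  ctr <- c(round(sp$lesions$z_mm[1] / sp$slice_increment) + 1,
           round(sp$lesions$row_mm[1] / sp$pixel_size) + 1,
           round(sp$lesions$col_mm[1] / sp$pixel_size) + 1)
  expect_equal(vox[ctr[1], ctr[2], ctr[3]], sp$lesions$peak_hu[1])
})

test_that("true volume is monotone non-decreasing in lesion radius", {
  vols <- vapply(seq(1, 5, by = 0.5), function(r) {
    sp <- phantom_spec(
      lesions = tibble::tibble(z_mm = 9, row_mm = 31.75, col_mm = 31.75,
                               radius_mm = r, peak_hu = 800),
      noise_sd = 0
    )
    make_native_phantom(sp)$truth$true_volume_mm3
  }, numeric(1))
  expect_true(all(diff(vols) >= 0))
  expect_gt(vols[length(vols)], vols[1])
})

test_that("CECT truth includes lesions above and excludes lesions below the dynamic margin", {
  mk <- function(peak) {
    phantom_spec(
      lumen = list(center_mm = c(31.75, 31.75), radius_mm = 15,
                   enhancement_hu = 350, native_blood_hu = 40),
      lesions = tibble::tibble(z_mm = 9, row_mm = 31.75, col_mm = 31.75,
                               radius_mm = 3, peak_hu = peak),
      noise_sd = 25, seed = 5L
    )
  }
  # 800 HU > 350 + 4*25 = 450: in the truth mask
  hi <- make_cect_phantom(mk(800))
  expect_gt(hi$truth$true_volume_mm3, 0)
  # 440 HU < 450: rendered but excluded from truth
  lo <- make_cect_phantom(mk(440))
  expect_equal(lo$truth$true_volume_mm3, 0)
  expect_true(any(lo$volume$voxels > 430))  # still present in the image
})

test_that("distractors are rendered but never part of the valve ground truth", {
  sp <- phantom_spec(
    distractors = tibble::tibble(z_mm = 30, row_mm = 55, col_mm = 55,
                                 radius_mm = 3, peak_hu = 900),
    noise_sd = 0
  )
  ph <- make_cect_phantom(sp)
  expect_true(any(ph$truth$distractor_mask))
  expect_equal(sum(ph$truth$calcium_mask & ph$truth$distractor_mask), 0)
  expect_true(any(ph$volume$voxels[ph$truth$distractor_mask] == 900))
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(noise_sd = -1), "noise_sd")
  expect_error(
    phantom_spec(lesions = tibble::tibble(z_mm = 0.5, row_mm = 31.75,
                                          col_mm = 31.75, radius_mm = 4,
                                          peak_hu = 800)),
    "outside"
  )
  expect_error(phantom_spec(grid_shape = c(20L, 128L, 128L)), "annulus")
  expect_error(
    make_cect_phantom(phantom_spec(
      lesions = tibble::tibble(z_mm = 7, row_mm = 31.75, col_mm = 31.75,
                               radius_mm = 3, peak_hu = 900),
      distractors = tibble::tibble(z_mm = 7, row_mm = 32, col_mm = 32,
                                   radius_mm = 3, peak_hu = 900)
    )),
    "overlap"
  )
})

test_that("paired cohorts are reproducible and sit on the line when noise-free", {
  m <- conversion_model(691, 1.83)
  a <- make_paired_cohort(n = 10, model = m, noise_sd = 0, seed = 7)
  expect_equal(a$native_agatston, 691 + 1.83 * a$cect_volume_mm3)
  b <- make_paired_cohort(n = 10, model = m, noise_sd = 0, seed = 7)
  expect_identical(a, b)
  expect_error(make_paired_cohort(n = 2), "n >= 3")
  expect_error(make_paired_cohort(n = 10, noise_sd = -5), "noise_sd")
})

test_that("agreement cohorts hit their target population ICC on average", {
  est <- vapply(1:200, function(i) {
    icc(make_agreement_cohort(n = 40, icc = 0.8, seed = i)[c("a", "b")])$estimate
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.8), 0.03)
})
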