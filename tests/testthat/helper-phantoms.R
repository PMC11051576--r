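# Shared fixtures, all generated in code.

# A small random phantom spec for oracle-equivalence and property tests:
# 44 slices at 0.75 mm keep the ROI plane (30 mm above the annulus) inside
# the grid while staying cheap to score by brute force.
random_small_spec <- function(seed, noise_sd = 20) {
  set.seed(seed)
  n_lesions <- sample(0:3, 1)
  extent_z <- 43 * 0.75
  extent_xy <- 23 * 0.5
  lesions <- if (n_lesions > 0) {
    tibble::tibble(
      z_mm = runif(n_lesions, 3, extent_z - 3),
      row_mm = runif(n_lesions, 3, extent_xy - 3),
      col_mm = runif(n_lesions, 3, extent_xy - 3),
      radius_mm = runif(n_lesions, 0.8, 2.5),
      peak_hu = runif(n_lesions, 150, 1200)
    )
  } else NULL
  phantom_spec(
    grid_shape = c(44L, 24L, 24L),
    pixel_size = 0.5, slice_increment = 0.75, slice_thickness = 1,
    lumen = list(center_mm = c(5.75, 5.75), radius_mm = 3,
                 enhancement_hu = 360, native_blood_hu = 40),
    background_hu = -50,
    lesions = lesions,
    noise_sd = noise_sd,
    annulus_slice_index = 2L,
    seed = seed
  )
}

# Thin-slice native volume whose every slice is the given 2D HU matrix,
# repeated `k` times so that one 3 mm slab reproduces it exactly.
block_volume <- function(slice_hu, pixel_size = 0.5, slice_increment = 0.75,
                         k = 4L) {
  d <- dim(slice_hu)
  vox <- aperm(array(slice_hu, dim = c(d[1], d[2], k)), c(3, 1, 2))
  ct_volume(vox, pixel_size = pixel_size, slice_increment = slice_increment,
            slice_thickness = slice_increment, tube_voltage = 120,
            modality = "native")
}
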