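test_that("phantom generation is deterministic given the spec", {
  a <- small_phantom(noise_sd = 20, blur_sd = 0.4, seed = 5)
  b <- small_phantom(noise_sd = 20, blur_sd = 0.4, seed = 5)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$mask, b$truth$mask)
  c <- small_phantom(noise_sd = 20, blur_sd = 0.4, seed = 6)
  expect_false(identical(a$volume$voxels, c$volume$voxels))
})

test_that("twin 2 mm tubes carry the analytic cylinder volume 0.5027 cm^3", {
  # spacing chosen so the 20 mm design length is exactly representable
  tb <- phantom_tubes(radius = 2, length = 20, spacing = c(0.5, 0.4, 0.4))
  expect_equal(tb$volume_cm3, 2 * pi * 2^2 * 20 / 1000, tolerance = 1e-12)
  expect_equal(tb$volume_cm3, 0.5027, tolerance = 1e-4)
  vox <- sum(tb$mask) * prod(tb$spacing) / 1000
  expect_equal(vox, tb$volume_cm3, tolerance = 0.02)
})

test_that("voxelised mask volume tracks the analytic volume at default spacing", {
  ph <- cached("default_clean", generate_phantom(phantom_spec()))
  vox <- sum(ph$truth$mask) * prod(ph$truth$spacing) / 1000
  expect_equal(vox, ph$truth$volumes_cm3$total, tolerance = 0.02)
  # regional sums close exactly in the analytic truth
  v <- ph$truth$volumes_cm3
  expect_equal(v$nares + v$midnasal + v$nasopharynx, v$total, tolerance = 1e-12)
})

test_that("a sealed nostril yields exactly one component not connected to the main passage", {
  ph <- small_phantom(sealed = "left")
  labs <- ph$truth$labels
  expect_equal(max(labs), 2L)
  expect_gt(sum(labs == 2L), 0)
  expect_gt(ph$truth$volumes_cm3$isolated, 0)
  iso_vox <- sum(labs == 2L) * prod(coarse_spacing) / 1000
  expect_equal(iso_vox, ph$truth$volumes_cm3$isolated, tolerance = 0.10)
})

test_that("stenosis series varies only the aperture gap", {
  ser <- stenosis_series(phantom_spec(), c(11.0, 4.7, 6.7), spacing = coarse_spacing)
  expect_equal(vapply(ser, function(p) p$truth$width_mm, 0), c(11.0, 4.7, 6.7))
  # same gap, same seed: identical phantoms
  twice <- stenosis_series(phantom_spec(), c(5.0, 5.0), spacing = coarse_spacing)
  expect_identical(twice[[1]]$volume$voxels, twice[[2]]$volume$voxels)
  # pyriform plane fixed across gaps
  pyr <- vapply(ser, function(p) p$truth$landmarks$pyriform, 0L)
  expect_equal(length(unique(pyr)), 1L)
})

test_that("geometry exceeding the grid is rejected", {
  expect_error(generate_phantom(phantom_spec(), spacing = coarse_spacing,
                                grid_shape = c(20, 40, 40)),
               "5 mm margin")
})

test_that("noise-free unsmoothed phantoms have an empty adaptive band", {
  ph <- clean_case()$ph
  v <- ph$volume$voxels
  expect_equal(sum(v >= -400 & v < -125), 0)
})
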