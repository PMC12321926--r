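test_that("ct_volume enforces its invariants", {
  ok <- ct_volume(array(0, c(2, 3, 4)), c(1, 0.5, 0.5))
  expect_s3_class(ok, "ct_volume")
  expect_equal(voxel_volume(ok), 0.25)
  expect_error(ct_volume(matrix(0, 2, 2), c(1, 1, 1)), "3-D")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, -1, 1)), "positive")
  expect_error(ct_volume(array(-2000, c(2, 2, 2)), c(1, 1, 1)), "HU")
  expect_error(ct_volume(array(5000, c(2, 2, 2)), c(1, 1, 1)), "HU")
})

test_that("reorient with zero angles is the identity and rejects large angles", {
  v <- clean_case()$ph$volume
  expect_identical(reorient(v, 0, 0), v)
  expect_error(reorient(v, 50, 0), "45")
  expect_error(reorient(v, 0, -46), "45")
})

test_that("rotating forward then back nearly recovers the thresholded air mask", {
  v <- clean_case()$ph$volume
  back <- reorient(reorient(v, ap_deg = 10), ap_deg = -10)
  expect_gte(dice(v$voxels < -400, back$voxels < -400), 0.99)
})

test_that("pyriform width survives a tilt-and-correct round trip", {
  ph <- small_phantom()
  tilted <- reorient(ph$volume, ap_deg = -7)
  fixed <- reorient(tilted, ap_deg = 7)
  m <- segment_airway(fixed)
  lm <- detect_landmarks(fixed, m)
  w <- pyriform_width(fixed, lm)
  # two trilinear resamplings smear the bone edge; allow two in-plane voxels
  expect_lt(abs(w$width_mm - ph$truth$width_mm), 2 * coarse_spacing[3] + 1e-9)
})

test_that("nearest-neighbour reorientation keeps masks binary", {
  v <- clean_case()$ph$volume
  r <- reorient(v, ap_deg = 5, method = "nearest")
  expect_true(all(r$voxels %in% unique(c(v$voxels, -1024))))
})
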