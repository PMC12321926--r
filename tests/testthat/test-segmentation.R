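test_that("the VOI covers every ground-truth airway slice and the central third laterally", {
  cc <- clean_case()
  voi <- cc$mask$voi
  tz <- which(apply(cc$ph$truth$mask, 1, any)) - 1L
  expect_true(all(tz >= voi$z_range[1] & tz < voi$z_range[2]))
  # lateral range is about one third of the head width on each slice
  d <- dim(cc$ph$volume$voxels)
  body <- cc$ph$volume$voxels > -400
  for (i in c(1L, nrow(voi$slices))) {
    z <- voi$slices$z[i]
    cols <- which(apply(body[z + 1L, , ], 2, any))
    w <- max(cols) - min(cols) + 1L
    expect_equal(voi$slices$x_hi[i] - voi$slices$x_lo[i], w / 3, tolerance = 2 / (w / 3))
  }
})

test_that("VOI selection is equivariant under lateral translation", {
  cc <- clean_case()
  v <- cc$ph$volume$voxels
  d <- dim(v)
  shift <- 8L
  v2 <- array(-1000, d)
  v2[, , (shift + 1):d[3]] <- v[, , 1:(d[3] - shift)]
  voi1 <- cc$mask$voi
  voi2 <- select_voi(ct_volume(v2, coarse_spacing))
  expect_equal(voi2$slices$x_lo, voi1$slices$x_lo + shift)
  expect_equal(voi2$z_range, voi1$z_range)
})

test_that("volumes without a head or without internal air are rejected", {
  expect_error(select_voi(ct_volume(array(-1000, c(10, 10, 10)), c(1, 1, 1))),
               "no body")
  solid <- ct_volume(array(40, c(30, 30, 30)), c(1, 1, 1))
  expect_error(select_voi(solid), "no airway candidate|no body")
})

test_that("nostril closure separates external from nasal air", {
  cc <- clean_case()
  ph <- cc$ph
  voi <- select_voi(ph$volume)
  cl <- close_nostrils(ph$volume, voi)
  # flood fill from a grid corner through non-excluded air never reaches truth
  air <- (ph$volume$voxels < -400) & !cl$excluded
  lab <- neonasal:::.cc_label_3d(air, dim(air), 26L)
  corner <- lab[1]
  expect_gt(corner, 0)
  expect_equal(sum(lab[ph$truth$mask] == corner), 0)
  # closure never excludes a ground-truth airway voxel
  expect_equal(sum(cl$excluded & ph$truth$mask), 0)
})

test_that("closure segments come in mirror-symmetric pairs; sealed noses have none", {
  cc <- clean_case()
  voi <- select_voi(cc$ph$volume)
  segs <- close_nostrils(cc$ph$volume, voi)$segments
  expect_gt(nrow(segs), 0)
  d3 <- dim(cc$ph$volume$voxels)[3]
  per_slice <- split(segs, segs$z)
  two_sided <- Filter(function(s) nrow(s) == 2, per_slice)
  expect_gt(length(two_sided), 0)
  for (s in two_sided[1:min(3, length(two_sided))]) {
    s <- s[order(s$x1), ]
    centre <- round(d3 / 2) - 0.5
    expect_equal(s$x1[1] - centre, -(s$x2[2] - centre + 1), tolerance = 2)
  }
  sealed <- small_phantom(sealed = c("left", "right"))
  voi_s <- select_voi(sealed$volume)
  expect_equal(nrow(close_nostrils(sealed$volume, voi_s)$segments), 0)
})

test_that("global threshold stage recovers the truth exactly on a clean phantom", {
  cc <- clean_case()
  ph <- cc$ph
  voi <- select_voi(ph$volume)
  cl <- close_nostrils(ph$volume, voi)
  ini <- global_threshold_segment(ph$volume, voi, cl)
  vi <- neonasal:::voi_indicator(voi)
  expect_identical(ini$mask, ph$truth$mask & vi)
  # nothing at or above the air threshold is ever segmented
  expect_equal(sum(ini$mask & ph$volume$voxels >= -400), 0)
})

test_that("air pockets smaller than the minimum object volume are removed", {
  ph <- small_phantom()
  v <- ph$volume$voxels
  # carve a ~1 mm^3 pocket (3 voxels at this spacing) in tissue inside the
  # VOI, well behind the nasopharynx so it cannot touch airway voxels
  voi <- select_voi(ph$volume)
  z <- voi$z_range[1] + 3L
  x <- as.integer(round(mean(c(voi$slices$x_lo[4], voi$slices$x_hi[4]))))
  pocket <- cbind(z + 1L, 100:102, x + 1L)
  stopifnot(all(v[pocket] > -400))
  v[pocket] <- -1000
  vol2 <- ct_volume(v, coarse_spacing)
  m <- segment_airway(vol2)
  expect_equal(sum(m$mask[pocket]), 0)
})

test_that("lowering the air threshold shrinks the initial mask", {
  ph <- cached("noisy_coarse",
               small_phantom(noise_sd = 20, blur_sd = 0.4, seed = 3))
  voi <- select_voi(ph$volume)
  cl <- close_nostrils(ph$volume, voi)
  a <- global_threshold_segment(ph$volume, voi, cl, nasal_config())
  b <- global_threshold_segment(ph$volume, voi, cl,
                                nasal_config(air_threshold_hu = -500))
  expect_true(all(b$mask <= a$mask))
  expect_lt(sum(b$mask), sum(a$mask))
})

test_that("adaptive expansion is monotone, idempotent and conserves voxels", {
  ph <- cached("noisy_coarse",
               small_phantom(noise_sd = 20, blur_sd = 0.4, seed = 3))
  voi <- select_voi(ph$volume)
  cl <- close_nostrils(ph$volume, voi)
  ini <- global_threshold_segment(ph$volume, voi, cl)
  exp1 <- adaptive_expand(ph$volume, ini)
  expect_true(all(ini$mask <= exp1$mask))
  expect_gt(sum(exp1$mask), sum(ini$mask))
  # fixed point: a second pass adds nothing
  exp2 <- adaptive_expand(ph$volume, exp1)
  expect_identical(exp2$mask, exp1$mask)
  # connectivity filtering keeps every expanded voxel in the label map
  fin <- filter_connected(exp1, voi)
  expect_true(all(main_mask(fin) <= exp1$mask))
  expect_equal(sum(fin$labels > 0L), sum(exp1$mask))
})

test_that("expansion band rules hold voxel-by-voxel", {
  ph <- cached("noisy_coarse",
               small_phantom(noise_sd = 20, blur_sd = 0.4, seed = 3))
  voi <- select_voi(ph$volume)
  cl <- close_nostrils(ph$volume, voi)
  ini <- global_threshold_segment(ph$volume, voi, cl)
  exp1 <- adaptive_expand(ph$volume, ini)
  added <- exp1$provenance == 2L
  v <- ph$volume$voxels
  expect_true(all(v[added] >= -400 & v[added] < -125))
  lm <- neonasal:::.local_band_mean(v, dim(v), -400, 0L)
  expect_true(all(v[added] < lm[added]))
})

test_that("isolated regions are flagged and excluded from measurements", {
  ph <- small_phantom(sealed = "left")
  m <- segment_airway(ph$volume)
  expect_equal(length(m$connected), 2L)
  expect_equal(sum(!m$connected), 1L)
  lm <- detect_landmarks(ph$volume, m)
  rep <- morphometry_report(ph$volume, m, lm)
  expect_gt(rep$report$isolated_cm3, 0)
  expect_equal(rep$report$isolated_cm3, ph$truth$volumes_cm3$isolated,
               tolerance = 0.10)
  # measured regional volumes exclude the sealed side
  expect_equal(rep$report$nares_cm3, ph$truth$volumes_cm3$nares,
               tolerance = 0.06)
})

test_that("an enclosed pocket inferior to the airway is excluded as oropharynx", {
  ph <- small_phantom(oropharynx_pocket = TRUE)
  m <- segment_airway(ph$volume)
  expect_equal(dice(main_mask(m), ph$truth$mask), 1)
})
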