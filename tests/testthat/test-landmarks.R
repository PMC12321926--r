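test_that("landmark ordering is enforced", {
  expect_error(landmark_set(5, 30, 20, 10, 60), "ordering")
  ok <- landmark_set(5, 20, 30, 10, 60)
  expect_s3_class(ok, "landmark_set")
})

test_that("the nasal tip is found at the designed slice and follows translation", {
  cc <- clean_case()
  voi <- cc$mask$voi
  tip <- detect_nasal_tip(cc$ph$volume, voi)
  expect_lte(abs(tip - cc$ph$truth$landmarks$tip), 1L)
  # translate the head superiorly by 3 slices
  v <- cc$ph$volume$voxels
  d <- dim(v)
  v2 <- array(-1000, d)
  v2[1:(d[1] - 3), , ] <- v[4:d[1], , ]
  vol2 <- ct_volume(v2, coarse_spacing)
  voi2 <- select_voi(vol2)
  expect_equal(detect_nasal_tip(vol2, voi2), tip - 3L)
})

test_that("pyriform plane detection matches the designed bone ring", {
  cc <- clean_case()
  expect_equal(cc$landmarks$pyriform, cc$ph$truth$landmarks$pyriform)
  # a raised bone threshold above the ring HU finds nothing
  expect_error(
    detect_pyriform_slice(cc$ph$volume, cc$mask$voi, cc$landmarks$tip,
                          nasal_config(bone_threshold_hu = 800)),
    "no pyriform bone")
})

test_that("a one-voxel bone speckle does not trigger pyriform detection", {
  ph <- small_phantom(bone_speckle = TRUE)
  m <- segment_airway(ph$volume)
  lm <- detect_landmarks(ph$volume, m)
  expect_equal(lm$pyriform, ph$truth$landmarks$pyriform)
})

test_that("choanae detection fires exactly at the designed width step", {
  cc <- clean_case()
  expect_equal(cc$landmarks$choanae, cc$ph$truth$landmarks$choanae)
})

test_that("the 1.5x boundary is inclusive and gradual tapers raise an error", {
  # synthetic main mask: widths 18, 18, 12, 12 mm posterior to anterior
  sp <- c(1, 0.6, 0.6)
  d <- c(10L, 8L, 50L)
  mk <- array(FALSE, d)
  wide <- 18 / sp[3]; narrow <- 12 / sp[3]
  at <- function(w) 25 + seq_len(w) - round(w / 2)
  mk[4:6, 3:4, at(narrow)] <- TRUE  # anterior slices hold the 12 mm region
  mk[4:6, 5:6, at(wide)] <- TRUE
  fm <- as_fake_mask(mk, sp)
  # first narrow slice met scanning posterior -> anterior (0-based index 3),
  # at the boundary ratio 18/12 = 1.5 exactly
  expect_equal(detect_choanae_slice(fm), 3L)

  # gradual taper: max adjacent ratio 1.2 -> no choanae
  mk2 <- array(FALSE, d)
  w <- 30
  for (j in 8:1) {
    mk2[4:6, j, at(max(4, round(w)))] <- TRUE
    w <- w / 1.15
  }
  expect_error(detect_choanae_slice(as_fake_mask(mk2, sp)), "choanae not found")
})

test_that("region partition is exhaustive, exclusive and local", {
  cc <- clean_case()
  reg <- partition_regions(cc$mask, cc$landmarks)
  expect_equal(sum(reg$regions > 0L), sum(main_mask(cc$mask)))
  expect_equal(sort(unique(reg$regions[reg$regions > 0L])), 1:3)
  # moving the choanae posterior by 2 slices moves exactly those slices'
  # voxels from nasopharynx to mid-nasal
  lm2 <- cc$landmarks
  lm2$choanae <- lm2$choanae + 2L
  reg2 <- partition_regions(cc$mask, lm2)
  moved <- sum(main_mask(cc$mask)[, cc$landmarks$choanae + (1:2), ])
  expect_equal(sum(reg2$regions == 2L) - sum(reg$regions == 2L), moved)
  expect_equal(sum(reg$regions == 3L) - sum(reg2$regions == 3L), moved)
})

test_that("per-region volumes match the analytic phantom truth", {
  ph <- cached("default_clean", generate_phantom(phantom_spec()))
  m <- cached("default_clean_mask", segment_airway(ph$volume))
  lm <- detect_landmarks(ph$volume, m)
  reg <- partition_regions(m, lm)
  vols <- regional_volumes(reg)
  truth <- ph$truth$volumes_cm3
  expect_equal(vols$nares, truth$nares, tolerance = 0.02)
  expect_equal(vols$midnasal, truth$midnasal, tolerance = 0.02)
  expect_equal(vols$nasopharynx, truth$nasopharynx, tolerance = 0.02)
})

test_that("landmark detection is invariant to tissue padding around the head", {
  cc <- clean_case()
  v <- cc$ph$volume$voxels
  d <- dim(v)
  v2 <- array(40, d + c(4L, 0L, 0L))
  v2[3:(d[1] + 2), , ] <- v
  vol2 <- ct_volume(v2, coarse_spacing)
  m2 <- segment_airway(vol2)
  lm2 <- detect_landmarks(vol2, m2)
  expect_equal(lm2$pyriform, cc$landmarks$pyriform)
  expect_equal(lm2$choanae, cc$landmarks$choanae)
  expect_equal(lm2$tip, cc$landmarks$tip + 2L)
})
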