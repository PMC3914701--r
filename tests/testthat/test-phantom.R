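test_that("concentric-sphere phantom has exact analytic ground truth", {
  ph <- sphere_phantom_1mm()
  expect_equal(ph$truth$cavity_volume_mm3, 4 / 3 * pi * 20^3)
  expect_equal(ph$truth$myocardium_volume_mm3,
               4 / 3 * pi * (30^3 - 20^3))
  pts <- rbind(c(25, 0, 0), c(0, -25, 0), c(0, 0, -25), c(17, 11, 7))
  expect_equal(ph$truth$thickness_fn(pts), rep(10, 4), tolerance = 1e-6)
})

test_that("voxel-counted volumes converge to analytic values (< 2% at 1 mm)", {
  ph <- sphere_phantom_1mm()
  vv <- voxel_volume(ph$labels)
  expect_lt(abs(sum(ph$labels$data == 1) * vv / ph$truth$cavity_volume_mm3 - 1),
            0.02)
  expect_lt(abs(sum(ph$labels$data == 2) * vv / ph$truth$myocardium_volume_mm3 - 1),
            0.02)
})

test_that("noiseless phantoms have exactly three gray levels; seeding is reproducible", {
  ph <- generate_phantom(sphere_spec(noise_sd = 0), spacing = c(2, 2, 2))
  expect_length(unique(as.vector(ph$grayscale$data)), 3L)

  a <- generate_phantom(sphere_spec(noise_sd = 15, seed = 42), spacing = c(2, 2, 2))
  b <- generate_phantom(sphere_spec(noise_sd = 15, seed = 42), spacing = c(2, 2, 2))
  d <- generate_phantom(sphere_spec(noise_sd = 15, seed = 43), spacing = c(2, 2, 2))
  expect_identical(a$grayscale$data, b$grayscale$data)
  expect_false(identical(a$grayscale$data, d$grayscale$data))
})

test_that("phantom spec validation rejects degenerate geometry", {
  expect_error(phantom_spec(wall_thickness = -1))
  expect_error(phantom_spec(wall_thickness = 2, wall_harmonic = 3),
               "non-positive")
  expect_error(generate_phantom(phantom_spec(), spacing = c(2, 2, 2),
                                grid_dim = c(10, 10, 10)),
               "exceeds")
})

test_that("ground-truth thickness is invariant to rigid pose", {
  sp0 <- sphere_spec()
  sp1 <- sphere_spec()
  sp1$pose_rotation_deg <- c(15, -10, 30)
  sp1$pose_translation_mm <- c(4, -6, 2)
  t0 <- phantom_truth_of(sp0)
  t1 <- phantom_truth_of(sp1)
  pts0 <- rbind(c(25, 0, 0), c(0, 0, 25), c(14, -14, 14))
  R <- cardiatlas:::rotation_xyz(sp1$pose_rotation_deg)
  pts1 <- sweep(pts0 %*% t(R), 2, sp1$pose_translation_mm, `+`)
  expect_equal(t0$thickness_fn(pts0), t1$thickness_fn(pts1), tolerance = 1e-6)
})

test_that("atlas pools are seeded, sized and degenerate-variation stable", {
  base <- phantom_spec(endo_semiaxes = c(18, 18, 26), wall_thickness = 7,
                       base_plane_mm = 14)
  pool <- generate_atlas_pool(base, 20, shape_variation_sd = 1.5,
                              rng_seed = 5, spacing = c(3, 3, 3))
  expect_length(pool, 20L)
  ids <- vapply(pool, function(a) a$atlas_id, character(1))
  expect_length(unique(ids), 20L)
  # geometrically distinct
  vols <- vapply(pool, function(a) sum(a$labels$data == 2), numeric(1))
  expect_gt(length(unique(vols)), 15L)

  pool2 <- generate_atlas_pool(base, 20, shape_variation_sd = 1.5,
                               rng_seed = 5, spacing = c(3, 3, 3))
  expect_identical(pool[[7]]$labels$data, pool2[[7]]$labels$data)

  frozen <- generate_atlas_pool(base, 3, shape_variation_sd = 0, rng_seed = 5,
                                spacing = c(3, 3, 3),
                                pose_variation = list(rot_sd_deg = 0,
                                                      trans_sd_mm = 0))
  expect_identical(frozen[[1]]$labels$data, frozen[[3]]$labels$data)
})

test_that("retest pairs: zero jitter and noise give identical acquisitions", {
  sp <- sphere_spec(noise_sd = 0)
  pair <- generate_retest_pair(sp, jitter = list(trans_sd_mm = 0, rot_sd_deg = 0),
                               rng_seed = 9, spacing = c(2, 2, 2))
  expect_identical(pair$acq1$grayscale$data, pair$acq2$grayscale$data)
  expect_identical(pair$acq1$labels$data, pair$acq2$labels$data)
})

test_that("retest pose offset recorded in the output matches the applied transform", {
  sp <- sphere_spec(noise_sd = 5)
  pair <- generate_retest_pair(sp, jitter = list(trans_sd_mm = 3, rot_sd_deg = 4),
                               rng_seed = 11, spacing = c(2.5, 2.5, 2.5))
  off <- pair$applied_offset
  expect_equal(pair$acq2$truth$spec$pose_rotation_deg,
               sp$pose_rotation_deg + off$rotation_deg)
  expect_equal(pair$acq2$truth$spec$pose_translation_mm,
               sp$pose_translation_mm + off$translation_mm)
  # landmarks move consistently with the recorded offset
  R <- cardiatlas:::rotation_xyz(sp$pose_rotation_deg + off$rotation_deg)
  apex_expected <- as.numeric(c(0, 0, -30) %*% t(R)) +
    sp$pose_translation_mm + off$translation_mm
  expect_equal(as.numeric(unclass(pair$acq2$landmarks)["apex", ]),
               apex_expected, tolerance = 1e-8)
})

test_that("harmonic wall modulation changes local truth thickness as prescribed", {
  sp <- sphere_spec()
  sp$wall_harmonic <- 2
  truth <- phantom_truth_of(sp)
  # P2(cos 0) = 1 at the pole, P2(cos pi/2) = -1/2 at the equator
  pole <- truth$thickness_fn(rbind(c(0, 0, 25)))
  equator <- truth$thickness_fn(rbind(c(25, 0, 0)))
  expect_equal(pole, 12, tolerance = 0.05)
  expect_equal(equator, 9, tolerance = 0.05)
})
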