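test_that("landmark alignment recovers identity and known transforms", {
  lm <- toy_landmarks()
  xf <- initialize_alignment(lm, lm)
  expect_equal(xf$rotation, diag(3), tolerance = 1e-10)
  expect_equal(xf$scale, 1, tolerance = 1e-10)
  expect_equal(xf$translation, c(0, 0, 0), tolerance = 1e-10)
  expect_lt(xf$residual_rms, 1e-10)

  R <- cardiatlas:::rotation_xyz(c(0, 0, 10))
  moved <- landmark_set(sweep(1.3 * unclass(lm) %*% t(R), 2, c(5, -2, 7), `+`))
  rec <- initialize_alignment(moved, lm)  # atlas lm -> target moved
  expect_equal(rec$rotation, R, tolerance = 1e-6)
  expect_equal(rec$scale, 1.3, tolerance = 1e-6)
  expect_equal(rec$translation, c(5, -2, 7), tolerance = 1e-6)
  expect_lt(rec$residual_rms, 1e-6)
})

test_that("alignment rejects incomplete or collinear landmark sets", {
  lm <- toy_landmarks()
  expect_error(initialize_alignment(unclass(lm)[1:5, ], lm), "six")
  line <- unclass(lm)
  line[, 1] <- 1:6; line[, 2] <- 2 * (1:6); line[, 3] <- -(1:6)
  expect_error(cardiatlas:::fit_similarity(line, line), "collinear")
})

test_that("patch weights follow the Gaussian similarity-distance kernel", {
  p <- fusion_params(similarity_bandwidth = 2, spatial_bandwidth = 3)
  a <- array(c(1, 2), c(2, 1, 1))
  expect_equal(patch_similarity_weight(a, a, c(0, 0, 0), p), 1)

  # hand-computed: SSD = 8 over n = 2 voxels, h^2 n = 8, zero offset -> e^-1
  b <- array(c(3, 4), c(2, 1, 1))
  expect_equal(patch_similarity_weight(a, b, c(0, 0, 0), p), exp(-1))

  # strictly decreasing in SSD at fixed offset
  w <- vapply(seq(0, 5, by = 0.5), function(delta)
    patch_similarity_weight(a, a + delta, c(1, 0, 0), p), numeric(1))
  expect_true(all(diff(w) < 0))
  # offset-only factor
  expect_equal(patch_similarity_weight(a, a, c(3, 0, 0), p), exp(-1))
})

test_that("self-segmentation against an identical atlas reproduces its labels", {
  pool <- coarse_pool()
  seg <- fuse_labels(pool[[1]]$intensity, pool[1], fusion_params(),
                     target_landmarks = pool[[1]]$landmarks)
  expect_equal(dice_coefficient(seg, pool[[1]]$labels, 1L), 1)
  expect_equal(dice_coefficient(seg, pool[[1]]$labels, 2L), 1)
})

test_that("fusion output is invariant to atlas ordering", {
  pool <- coarse_pool()
  seg_a <- fuse_labels(pool[[4]]$intensity, pool[1:3], fusion_params(),
                       target_landmarks = pool[[4]]$landmarks)
  seg_b <- fuse_labels(pool[[4]]$intensity, pool[c(3, 1, 2)], fusion_params(),
                       target_landmarks = pool[[4]]$landmarks)
  expect_identical(seg_a$data, seg_b$data)
})

test_that("volumetry applies the voxel volume, 1.05 g/mL density and BSA index", {
  arr <- array(0L, c(20, 10, 10))
  arr[1:10, , ] <- 1L            # 1000 cavity voxels
  arr[11:20, , ] <- 2L           # 1000 myocardium voxels
  lab <- volume_image(arr, spacing = c(1, 1, 1))
  v <- compute_volumetry(lab, body_surface_area_m2 = 2)
  expect_equal(v$lv_mass_g, 1.05)
  expect_equal(v$lvedv_ml, 1)
  expect_equal(v$lvmi_g_m2, 0.525)

  # LVEDV 170 mL at BSA 2 -> LVEDVI 85
  arr2 <- array(0L, c(100, 100, 18))
  arr2[, , 1:17] <- 1L
  arr2[, , 18] <- 2L
  lab2 <- volume_image(arr2, spacing = c(1, 1, 1))
  v2 <- compute_volumetry(lab2, 2)
  expect_equal(v2$lvedvi_ml_m2, 85)

  empty <- volume_image(array(1L, c(4, 4, 4)), c(1, 1, 1))
  expect_error(compute_volumetry(empty, 2), "myocardium")
  expect_error(compute_volumetry(lab, 0), "body_surface_area")
})

test_that("phantom volumetry matches analytic shell volumes within discretisation", {
  ph <- sphere_phantom_1mm()
  v <- compute_volumetry(ph$labels, body_surface_area_m2 = 1.8)
  expect_equal(v$lvedv_ml, ph$truth$cavity_volume_mm3 / 1000, tolerance = 0.02)
  expect_equal(v$lv_mass_g, 1.05 * ph$truth$myocardium_volume_mm3 / 1000,
               tolerance = 0.02)
})
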