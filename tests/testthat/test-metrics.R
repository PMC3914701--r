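mask_volume <- function(idx_true, dims = c(5, 5, 4), code = 1L) {
  arr <- array(0L, dims)
  arr[idx_true] <- code
  volume_image(arr, spacing = c(1, 1, 1))
}

test_that("Dice handles perfect, partial, disjoint and empty overlap", {
  a <- mask_volume(1:10)
  b <- mask_volume(5:14)          # |A|=|B|=10, intersection 6
  expect_equal(dice_coefficient(a, a, 1L), 1)
  expect_equal(dice_coefficient(a, b, 1L), 0.6)
  expect_equal(dice_coefficient(a, mask_volume(50:59), 1L), 0)
  # symmetry
  expect_equal(dice_coefficient(a, b, 1L), dice_coefficient(b, a, 1L))
  # both empty -> 1, one empty -> 0
  empty <- mask_volume(integer(0))
  expect_equal(dice_coefficient(empty, empty, 1L), 1)
  expect_equal(dice_coefficient(a, empty, 1L), 0)
  # grid mismatch
  expect_error(dice_coefficient(a, mask_volume(1:10, dims = c(4, 5, 4)), 1L),
               "grids")
})

test_that("surface distances: identity, rigid offset, and stochastic oracle", {
  m <- analytic_sphere_mesh(15, spacing = 2.5, half_extent = 20)
  self <- surface_distance(m, m)
  expect_equal(self$mean_mm, 0)
  expect_equal(self$sd_mm, 0)

  shifted <- surface_mesh(sweep(m$points, 2, c(1, 0, 0), `+`), m$triangles)
  d <- surface_distance(shifted, m, mode = "corresponded")
  expect_equal(d$mean_mm, 1, tolerance = 1e-12)
  expect_equal(d$sd_mm, 0, tolerance = 1e-12)

  # per-axis N(0, 0.5^2) perturbation: corresponded mean ~ E||eps||
  set.seed(4)
  pert <- surface_mesh(m$points + matrix(rnorm(length(m$points), 0, 0.5),
                                         ncol = 3), m$triangles)
  dp <- surface_distance(pert, m, mode = "corresponded")
  mc <- mean(sqrt(rowSums(matrix(rnorm(3e5, 0, 0.5), ncol = 3)^2)))
  expect_equal(dp$mean_mm, mc, tolerance = 0.05)

  expect_error(surface_distance(surface_mesh(m$points[1:10, ],
                                             matrix(c(1, 2, 3), 1)), m),
               "point counts")
})

test_that("contrast ratio follows the contrast-to-noise form", {
  d <- 5 / sqrt(2)  # two-point samples with SD exactly 5
  r1 <- c(100 - d, 100 + d)
  r2 <- c(50 - d, 50 + d)
  expect_equal(contrast_ratio(r1, r2), 50 / sqrt(50))
  expect_equal(contrast_ratio(r1, r1), 0)
  # doubling both SDs halves CR
  r1w <- c(100 - 2 * d, 100 + 2 * d); r2w <- c(50 - 2 * d, 50 + 2 * d)
  expect_equal(contrast_ratio(r1w, r2w), contrast_ratio(r1, r2) / 2)
  # shift invariance and 1/k scaling about the means
  expect_equal(contrast_ratio(r1 + 13, r2 + 13), contrast_ratio(r1, r2))
  expect_equal(contrast_ratio(r1 / 4, r2 / 4), contrast_ratio(r1, r2))
  sc1 <- 100 + (r1 - 100) / 4; sc2 <- 50 + (r2 - 50) / 4
  expect_equal(contrast_ratio(sc1, sc2), 4 * contrast_ratio(r1, r2))
  expect_error(contrast_ratio(numeric(0), r2), "non-empty")
  expect_error(contrast_ratio(c(1, 1, 1), c(2, 2, 2)), "zero pooled SD")
})

test_that("phantom contrast ratio is near its design value", {
  ph <- generate_phantom(sphere_spec(noise_sd = 20, seed = 5),
                        spacing = c(2, 2, 2))
  blood <- ph$grayscale$data[ph$labels$data == 1]
  myo <- ph$grayscale$data[ph$labels$data == 2]
  cr <- contrast_ratio(blood, myo)
  expect_equal(cr, 300 / sqrt(800), tolerance = 0.05)
})

test_that("thin-slice leave-one-out accuracy beats the thick-slab emulation", {
  pool <- coarse_pool()
  acc3 <- leave_one_out_accuracy(pool, fusion_params(), emulate_2d = FALSE)
  acc2 <- suppressWarnings(
    leave_one_out_accuracy(pool, fusion_params(), emulate_2d = TRUE))
  expect_equal(acc3$arm, rep("3D", 4))
  expect_equal(acc2$arm, rep("2D", 4))
  expect_gt(mean(acc3$dice_myocardium), mean(acc2$dice_myocardium))
  expect_gt(mean(acc3$dice_lv_cavity), mean(acc2$dice_lv_cavity))
})

test_that("leave-one-out on identical atlases gives Dice 1 and one report per atlas", {
  base <- phantom_spec(endo_semiaxes = c(18, 18, 26), wall_thickness = 7,
                       base_plane_mm = 14, rng_seed = 8)
  ph <- generate_phantom(base, spacing = c(2.5, 2.5, 2.5))
  one <- atlas(ph$grayscale, ph$labels, ph$landmarks, atlas_id = "a")
  pool <- list(one, one, one)
  acc <- leave_one_out_accuracy(pool, fusion_params())
  expect_equal(nrow(acc), 3L)
  expect_true(all(acc$dice_lv_cavity == 1))
  expect_true(all(acc$dice_myocardium == 1))
  expect_error(leave_one_out_accuracy(pool[1]), "two atlases")
})
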