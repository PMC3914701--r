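test_that("NIfTI round-trip preserves data, spacing and origin", {
  tmp <- withr::local_tempdir()
  set.seed(1)
  gray <- volume_image(array(rnorm(16 * 14 * 10), c(16, 14, 10)),
                       spacing = c(1.2, 1.2, 2.0), origin = c(-9, -8, -10))
  f <- file.path(tmp, "gray.nii.gz")
  write_volume(gray, f)
  back <- read_volume(f)
  expect_equal(back$spacing, c(1.2, 1.2, 2.0), tolerance = 1e-6)
  expect_equal(back$origin, gray$origin, tolerance = 1e-6)
  expect_lt(max(abs(back$data - gray$data)), 1e-6)

  labs <- volume_image(array(sample(0:3, 16 * 14 * 10, TRUE), c(16, 14, 10)),
                       spacing = c(1.2, 1.2, 2.0))
  fl <- file.path(tmp, "labels.nii.gz")
  write_volume(labs, fl)
  expect_identical(as.integer(read_volume(fl)$data), as.integer(labs$data))
})

test_that("read_volume rejects malformed and non-3D input", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "bad.nii")
  writeLines("this is not a nifti", bad)
  expect_error(suppressWarnings(read_volume(bad)), "malformed|NIfTI")
  expect_error(read_volume(file.path(tmp, "missing.nii")), "not found")

  f2d <- file.path(tmp, "slice.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(64), 8, 8)), f2d)
  expect_error(read_volume(f2d), "3D")
})

test_that("volume_image validates geometry and maps indices to mm", {
  expect_error(volume_image(array(0, c(4, 4)), c(1, 1, 1)), "3D")
  expect_error(volume_image(array(0, c(4, 4, 4)), c(1, -1, 1)), "spacing")
  vol <- volume_image(array(0, c(4, 4, 4)), spacing = c(1.5, 2, 2.5),
                      origin = c(10, 20, 30))
  idx <- rbind(c(0, 0, 0), c(2, 1, 3))
  w <- voxel_to_world(vol, idx)
  expect_equal(w[1, ], c(10, 20, 30))
  expect_equal(w[2, ], c(13, 22, 37.5))
  expect_equal(world_to_voxel(vol, w), idx)
  expect_equal(voxel_volume(vol), 7.5)
})

test_that("stack emulation pools 8 mm slabs with 2 mm gaps from 2 mm slices", {
  set.seed(2)
  nz <- 40
  vol <- volume_image(array(rnorm(8 * 8 * nz), c(8, 8, nz)),
                      spacing = c(1.2, 1.2, 2))
  out <- resample_to_stack(vol, slice_thickness_mm = 8, gap_mm = 2)
  expect_equal(out$spacing[3], 10)
  # slab s pools input slices 5s-4 .. 5s-1 (4 slices of a 5-slice pitch)
  for (s in seq_len(dim(out$data)[3])) {
    sel <- (s - 1) * 5 + 1:4
    expect_equal(out$data[, , s], apply(vol$data[, , sel], c(1, 2), mean))
  }
})

test_that("stack emulation is the identity at native sampling and preserves constants", {
  vol <- volume_image(array(rnorm(6 * 6 * 12), c(6, 6, 12)),
                      spacing = c(1, 1, 2), origin = c(0, 0, 5))
  out <- resample_to_stack(vol, slice_thickness_mm = 2, gap_mm = 0)
  expect_equal(out$data, vol$data)
  expect_equal(out$spacing, vol$spacing)
  expect_equal(out$origin, vol$origin)

  const <- volume_image(array(7, c(5, 5, 20)), spacing = c(1, 1, 1))
  pooled <- resample_to_stack(const, 4, 1)
  expect_true(all(pooled$data == 7))
})

test_that("label stacks use majority vote with ties toward the lower code", {
  arr <- array(0L, c(2, 2, 4))
  arr[1, 1, ] <- c(2L, 2L, 1L, 1L)  # tie 1 vs 2 -> 1
  arr[2, 1, ] <- c(2L, 2L, 2L, 1L)  # majority 2
  arr[1, 2, ] <- c(0L, 0L, 3L, 3L)  # tie 0 vs 3 -> 0
  vol <- volume_image(arr, spacing = c(1, 1, 1))
  out <- resample_to_stack(vol, 4, 0, kind = "labels")
  expect_equal(dim(out$data)[3], 1L)
  expect_identical(out$data[1, 1, 1], 1)
  expect_identical(out$data[2, 1, 1], 2)
  expect_identical(out$data[1, 2, 1], 0)
})

test_that("a trailing partial slab is truncated with a warning", {
  vol <- volume_image(array(1, c(4, 4, 11)), spacing = c(1, 1, 1))
  expect_warning(out <- resample_to_stack(vol, 4, 1), "truncated")
  expect_equal(dim(out$data)[3], 3L)
})

test_that("landmark sets validate and round-trip through JSON", {
  lm <- toy_landmarks()
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "lm.json")
  write_landmarks(lm, f)
  back <- read_landmarks(f)
  expect_equal(unclass(back), unclass(lm))

  expect_error(landmark_set(unclass(lm)[1:5, ]), "six")
  dup <- unclass(lm); dup[2, ] <- dup[1, ]
  expect_error(landmark_set(dup), "distinct")
  inf <- unclass(lm); inf[3, 1] <- Inf
  expect_error(landmark_set(inf), "finite")
})

test_that("meshes round-trip through ASCII PLY with optional scalars", {
  m <- analytic_sphere_mesh(12, spacing = 3, half_extent = 15)
  tmp <- withr::local_tempdir()
  f <- file.path(tmp, "m.ply")
  write_ply(m, f, scalars = seq_len(nrow(m$points)) / 7)
  back <- read_ply(f)
  expect_equal(nrow(back$points), nrow(m$points))
  expect_identical(back$triangles, m$triangles)
  expect_lt(max(abs(back$points - m$points)), 1e-4)
})
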