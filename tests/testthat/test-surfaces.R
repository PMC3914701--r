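test_that("sphere-shell surfaces have correct radii and areas", {
  ph <- sphere_phantom_1mm()
  surf <- extract_surfaces(ph$labels)
  re <- sqrt(rowSums(surf$endo$points^2))
  rp <- sqrt(rowSums(surf$epi$points^2))
  expect_lt(max(abs(re - 20)), 0.5)   # within half a voxel
  expect_lt(max(abs(rp - 30)), 0.5)
  expect_lt(abs(mesh_area(surf$endo) / (4 * pi * 20^2) - 1), 0.03)
  expect_lt(abs(mesh_area(surf$epi) / (4 * pi * 30^2) - 1), 0.03)
})

test_that("surface extraction rejects empty label maps", {
  empty <- volume_image(array(0L, c(8, 8, 8)), c(1, 1, 1))
  expect_error(extract_surfaces(empty), "myocardium")
  no_cavity <- volume_image(array(2L, c(8, 8, 8)), c(1, 1, 1))
  expect_error(extract_surfaces(no_cavity), "cavity")
})

test_that("template from identical atlases equals any member", {
  base <- phantom_spec(endo_semiaxes = c(18, 18, 26), wall_thickness = 7,
                       base_plane_mm = 14)
  pool <- generate_atlas_pool(base, 3, shape_variation_sd = 0, rng_seed = 2,
                              spacing = c(2, 2, 2),
                              pose_variation = list(rot_sd_deg = 0,
                                                    trans_sd_mm = 0))
  tmpl <- build_template(pool, template_spacing = c(3, 3, 3))
  # template points lie on the member's endo surface
  surf <- extract_surfaces(pool[[1]]$labels)
  pr <- cardiatlas:::project_points_cpp(tmpl$endo$points, surf$endo$points,
                                        surf$endo$triangles)
  # agreement is limited by the template's own 3 mm meshing resolution
  expect_lt(mean(pr$distance), 0.25)
  expect_lt(max(pr$distance), 1.0)
})

test_that("template of two aligned spheres averages their radii", {
  mk <- function(r, seed) {
    sp <- phantom_spec(endo_semiaxes = c(r, r, r), wall_thickness = 8,
                       base_plane_mm = r + 12, noise_sd = 0, rng_seed = seed)
    ph <- generate_phantom(sp, spacing = c(1.5, 1.5, 1.5))
    atlas(ph$grayscale, ph$labels, ph$landmarks,
          atlas_id = paste0("r", r), truth = ph$truth)
  }
  # suppress the similarity-scale component so the mean is a plain average
  tmpl <- build_template(list(mk(20, 1), mk(22, 2)),
                         template_spacing = c(2.5, 2.5, 2.5))
  r_t <- sqrt(rowSums(tmpl$endo$points^2))
  expect_equal(mean(r_t), 21, tolerance = 0.35)
})

test_that("registering a template to itself is the identity", {
  tmpl <- fixture("small_template", {
    pool <- coarse_pool()
    build_template(pool[1:3], template_spacing = c(3, 3, 3))
  })
  reg <- register_template(tmpl, tmpl$endo, tmpl$epi)
  expect_lt(max(abs(reg$endo$points - tmpl$endo$points)), 1e-6)
  expect_lt(max(abs(reg$epi$points - tmpl$epi$points)), 1e-6)
  expect_lt(reg$residual_rms, 1e-8)
})

test_that("registration recovers a known uniform scaling", {
  tmpl <- fixture("small_template", {
    pool <- coarse_pool()
    build_template(pool[1:3], template_spacing = c(3, 3, 3))
  })
  scaled_endo <- surface_mesh(tmpl$endo$points * 1.1, tmpl$endo$triangles,
                              "endocardium")
  scaled_epi <- surface_mesh(tmpl$epi$points * 1.1, tmpl$endo$triangles,
                             "epicardium")
  reg <- register_template(tmpl, scaled_endo, scaled_epi)
  expect_equal(reg$transform$scale, 1.1, tolerance = 1e-3)
  # projected points lie on the target surface
  pr <- cardiatlas:::project_points_cpp(reg$endo$points, scaled_endo$points,
                                        scaled_endo$triangles)
  expect_lt(max(pr$distance), 1e-6)
})

test_that("thickness on analytic concentric spheres is 10 mm at every point", {
  endo <- analytic_sphere_mesh(20, spacing = 2)
  # radial correspondence: endo vertex u maps to epi point 30u
  u <- endo$points / sqrt(rowSums(endo$points^2))
  cor_endo <- surface_mesh(20 * u, endo$triangles, "endocardium")
  cor_epi <- surface_mesh(30 * u, endo$triangles, "epicardium")
  tm <- measure_thickness(cor_endo, cor_epi)
  expect_equal(length(tm$values), nrow(cor_endo$points))
  expect_lt(max(abs(tm$values - 10)), 0.2)
})

test_that("thickness is invariant under rigid motion of both meshes", {
  endo <- analytic_sphere_mesh(20, spacing = 2)
  epi <- analytic_sphere_mesh(30, spacing = 2)
  u <- endo$points / sqrt(rowSums(endo$points^2))
  cor_endo <- surface_mesh(20 * u, endo$triangles, "endocardium")
  cor_epi <- surface_mesh(30 * u, endo$triangles, "epicardium")
  t0 <- measure_thickness(cor_endo, cor_epi)
  R <- cardiatlas:::rotation_xyz(c(20, -35, 10))
  shift <- c(12, -5, 40)
  m_endo <- surface_mesh(sweep(cor_endo$points %*% t(R), 2, shift, `+`),
                         endo$triangles, "endocardium")
  m_epi <- surface_mesh(sweep(cor_epi$points %*% t(R), 2, shift, `+`),
                        endo$triangles, "epicardium")
  t1 <- measure_thickness(m_endo, m_epi)
  expect_lt(max(abs(t1$values - t0$values)), 1e-6)
})

test_that("thickness maps tidy into per-point tibbles", {
  tm <- thickness_map(c(8, 8.5, 9), subject_id = "s1", acquisition_id = "a1")
  td <- tidy(tm)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$thickness_mm, c(8, 8.5, 9))
  expect_equal(td$point_index, 1:3)
})
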