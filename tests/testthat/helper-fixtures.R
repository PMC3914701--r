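# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# concentric-sphere shell spec: endo r = 20, wall 10, untruncated
sphere_spec <- function(noise_sd = 0, seed = 1L) {
  phantom_spec(endo_semiaxes = c(20, 20, 20), wall_thickness = 10,
               base_plane_mm = 35, noise_sd = noise_sd, rng_seed = seed)
}

sphere_phantom_1mm <- function() {
  fixture("sphere_phantom_1mm",
          generate_phantom(sphere_spec(), spacing = c(1, 1, 1)))
}

# small LV-like pool at coarse spacing for segmentation tests
coarse_pool <- function() {
  fixture("coarse_pool", {
    base <- phantom_spec(endo_semiaxes = c(22, 22, 38), wall_thickness = 8,
                         base_plane_mm = 20)
    generate_atlas_pool(base, 4, shape_variation_sd = 1.5, rng_seed = 3,
                        spacing = c(2.2, 2.2, 2.2))
  })
}

# generic well-conditioned landmark set used for same-grid fusion tests
toy_landmarks <- function(scale = 10) {
  landmark_set(rbind(apex = c(0, 0, -scale),
                     base_center = c(0, 0, scale),
                     mitral_lateral = c(scale, 0, scale),
                     mitral_septal = c(-scale, 0, scale),
                     rv_insertion_anterior = c(0, scale, 0),
                     rv_insertion_inferior = c(0, -scale, 0)))
}

phantom_truth_of <- function(spec) cardiatlas:::phantom_truth(spec)

# analytic concentric-sphere meshes from a smooth field (sub-voxel accurate)
analytic_sphere_mesh <- function(radius, spacing = 1, half_extent = 34) {
  n <- ceiling(2 * half_extent / spacing) + 1
  ax <- seq(-half_extent, half_extent, length.out = n)
  field <- array(0, c(n, n, n))
  for (k in seq_len(n))
    field[, , k] <- sqrt(outer(ax^2, ax^2, `+`) + ax[k]^2)
  h <- ax[2] - ax[1]
  res <- cardiatlas:::march_tetrahedra_cpp(as.numeric(-field), dim(field),
                                           -radius, rep(h, 3),
                                           c(ax[1], ax[1], ax[1]))
  surface_mesh(res$points, res$triangles)
}
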