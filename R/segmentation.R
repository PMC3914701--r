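#' Labeled atlas
#'
#' An intensity volume with its manual label map, landmarks and id. The
#' intensity and label volumes must share grid, spacing and origin.
#'
#' @param intensity,labels [volume_image()]s on a common grid.
#' @param landmarks a [landmark_set()].
#' @param atlas_id identifier string.
#' @param truth optional generator ground truth (phantom atlases).
#' @return object of class `atlas`.
#' @export
atlas <- function(intensity, labels, landmarks, atlas_id = "atlas", truth = NULL) {
  stopifnot(inherits(intensity, "volume_image"), inherits(labels, "volume_image"),
            inherits(landmarks, "landmark_set"))
  if (!identical(dim(intensity$data), dim(labels$data)) ||
      max(abs(intensity$spacing - labels$spacing)) > 1e-9 ||
      max(abs(intensity$origin - labels$origin)) > 1e-9)
    stop("intensity and label volumes must share grid, spacing and origin",
         call. = FALSE)
  assert_label_volume(labels)
  structure(list(intensity = intensity, labels = labels, landmarks = landmarks,
                 atlas_id = atlas_id, truth = truth), class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat("<atlas> ", x$atlas_id, ": ", paste(dim(x$intensity$data), collapse = " x "),
      " voxels\n", sep = "")
  invisible(x)
}

#' Patch-fusion parameters
#'
#' Controls the exhaustive windowed patch search used for label fusion.
#' Patch and search sizes are physical (mm) and converted per volume to odd
#' voxel extents, so 2 mm and 10 mm z-sampled inputs use comparable physical
#' neighbourhoods. The candidate weight is
#' `exp(-SSD / (h^2 n)) * exp(-|offset|^2 / s^2)` with `h` the similarity
#' bandwidth (intensity units), `s` the spatial bandwidth (mm) and `n` the
#' patch voxel count.
#'
#' @param patch_size_mm cubic patch edge length in mm (default 5).
#' @param search_radius_mm half-width of the search window in mm.
#' @param n_best_patches candidates retained per atlas per voxel.
#' @param similarity_bandwidth `h`, intensity units.
#' @param spatial_bandwidth `s`, mm.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(patch_size_mm = 5, search_radius_mm = 6,
                          n_best_patches = 5, similarity_bandwidth = 15,
                          spatial_bandwidth = 10) {
  stopifnot(patch_size_mm > 0, search_radius_mm > 0, n_best_patches >= 1,
            similarity_bandwidth > 0, spatial_bandwidth > 0)
  structure(list(patch_size_mm = patch_size_mm,
                 search_radius_mm = search_radius_mm,
                 n_best_patches = as.integer(n_best_patches),
                 similarity_bandwidth = similarity_bandwidth,
                 spatial_bandwidth = spatial_bandwidth),
            class = "fusion_params")
}

#' Landmark-based similarity alignment
#'
#' Least-squares similarity transform (rotation, isotropic scale,
#' translation) mapping the atlas landmarks onto the target landmarks
#' (Umeyama closed form). The residual RMS after alignment is attached.
#'
#' @param target_landmarks,atlas_landmarks [landmark_set()]s (or 6 x 3
#'   matrices) with matching point order.
#' @return object of class `similarity_transform`: fields `rotation` (3 x 3),
#'   `scale`, `translation`, `residual_rms`.
#' @export
initialize_alignment <- function(target_landmarks, atlas_landmarks) {
  X <- as.matrix(unclass(atlas_landmarks))
  Y <- as.matrix(unclass(target_landmarks))
  if (nrow(X) != 6L || nrow(Y) != 6L)
    stop("both landmark sets must contain exactly six points", call. = FALSE)
  fit_similarity(X, Y)
}

# Umeyama similarity fit X -> Y
fit_similarity <- function(X, Y) {
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  Sigma <- crossprod(Yc, Xc) / n
  sv <- svd(Sigma)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) landmark configuration", call. = FALSE)
  S <- diag(3)
  if (det(sv$u) * det(sv$v) < 0) S[3, 3] <- -1
  R <- sv$u %*% S %*% t(sv$v)
  var_x <- mean(rowSums(Xc^2))
  s <- sum(sv$d * diag(S)) / var_x
  t <- my - s * as.numeric(R %*% mx)
  fitted <- sweep(s * X %*% t(R), 2, t, `+`)
  structure(list(rotation = R, scale = s, translation = t,
                 residual_rms = sqrt(mean(rowSums((Y - fitted)^2)))),
            class = "similarity_transform")
}

#' Apply / invert a similarity transform
#' @param transform a `similarity_transform`.
#' @param points n x 3 matrix.
#' @export
apply_transform <- function(transform, points) {
  sweep(transform$scale * rbind(points) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(transform) {
  Rin <- t(transform$rotation)
  sin_ <- 1 / transform$scale
  structure(list(rotation = Rin, scale = sin_,
                 translation = -sin_ * as.numeric(Rin %*% transform$translation),
                 residual_rms = transform$residual_rms),
            class = "similarity_transform")
}

#' Patch similarity weight
#'
#' The weight of one candidate atlas patch for one target patch:
#' `exp(-SSD / (h^2 n)) * exp(-|offset|^2 / s^2)`, where SSD is the
#' sum of squared intensity differences over the `n` patch voxels and
#' `offset` the physical displacement between the patch centres.
#' Identical patches at zero offset attain the maximum weight 1.
#'
#' @param target_patch,atlas_patch numeric arrays of identical size.
#' @param spatial_offset_mm length-3 physical offset (mm).
#' @param params a [fusion_params()].
#' @return non-negative scalar weight.
#' @export
patch_similarity_weight <- function(target_patch, atlas_patch,
                                    spatial_offset_mm, params) {
  stopifnot(identical(dim(target_patch), dim(atlas_patch)) ||
              length(target_patch) == length(atlas_patch))
  ssd <- sum((target_patch - atlas_patch)^2)
  n <- length(target_patch)
  exp(-ssd / (params$similarity_bandwidth^2 * n)) *
    exp(-sum(spatial_offset_mm^2) / params$spatial_bandwidth^2)
}

# physical patch edge length -> per-axis voxel radius (odd extent >= 1)
patch_voxel_radius <- function(size_mm, spacing) {
  pmax(1L, as.integer(floor(size_mm / (2 * spacing))))
}

# physical search radius -> per-axis voxel radius (>= 1)
search_voxel_radius <- function(radius_mm, spacing) {
  pmax(1L, as.integer(floor(radius_mm / spacing)))
}

# resample an atlas onto the target grid through a similarity transform
# (trilinear intensity, nearest-neighbour labels)
resample_atlas_to_target <- function(atl, transform, target) {
  d <- dim(target$data)
  ii <- seq_len(d[1]) - 1; jj <- seq_len(d[2]) - 1; kk <- seq_len(d[3]) - 1
  idx <- cbind(rep(ii, times = d[2] * d[3]),
               rep(rep(jj, each = d[1]), times = d[3]),
               rep(kk, each = d[1] * d[2]))
  world <- voxel_to_world(target, idx)
  atlas_world <- apply_transform(invert_transform(transform), world)
  avox <- world_to_voxel(atl$intensity, atlas_world)
  bg <- atl$intensity$data[1, 1, 1]
  intens <- sample_volume_cpp(as.numeric(atl$intensity$data),
                              dim(atl$intensity$data), avox,
                              nearest = FALSE, fill = bg)
  labs <- sample_volume_cpp(as.numeric(atl$labels$data),
                            dim(atl$labels$data), avox,
                            nearest = TRUE, fill = 0)
  list(intensity = array(intens, d), labels = array(as.integer(labs), d))
}

#' Multi-atlas patch-based label fusion
#'
#' Segments a target grayscale volume against a pool of labeled atlases.
#' Each atlas is first aligned to the target by the landmark similarity
#' transform and resampled onto the target grid; then, for every target
#' voxel, all atlas patches within the search window are weighted by
#' intensity similarity and spatial proximity, the `n_best_patches` heaviest
#' candidates per atlas vote for the label at their centre, and the fused
#' label is the weight-argmax (ties toward the lower label code). The result
#' is deterministic and invariant to atlas ordering.
#'
#' @param target grayscale [volume_image()].
#' @param atlases list of [atlas()] objects (>= 1).
#' @param params a [fusion_params()].
#' @param target_landmarks [landmark_set()] on the target, used for
#'   initialisation.
#' @return label [volume_image()] on the target grid, with an `alignment`
#'   attribute holding the per-atlas residual RMS.
#' @export
fuse_labels <- function(target, atlases, params = fusion_params(),
                        target_landmarks) {
  stopifnot(inherits(target, "volume_image"), length(atlases) >= 1)
  spacing <- target$spacing
  patch_r <- patch_voxel_radius(params$patch_size_mm, spacing)
  search_r <- search_voxel_radius(params$search_radius_mm, spacing)
  res <- lapply(atlases, function(a) {
    xf <- initialize_alignment(target_landmarks, a$landmarks)
    rs <- resample_atlas_to_target(a, xf, target)
    list(xf = xf, rs = rs)
  })
  fused <- fuse_labels_cpp(as.numeric(target$data), dim(target$data),
                           lapply(res, function(r) as.numeric(r$rs$intensity)),
                           lapply(res, function(r) as.integer(r$rs$labels)),
                           patch_r, search_r, params$n_best_patches,
                           params$similarity_bandwidth^2,
                           params$spatial_bandwidth^2, spacing)
  out <- volume_image(array(as.integer(fused), dim(target$data)),
                      spacing = spacing, origin = target$origin)
  attr(out, "alignment") <- tibble::tibble(
    atlas_id = vapply(atlases, function(a) a$atlas_id, character(1)),
    residual_rms = vapply(res, function(r) r$xf$residual_rms, numeric(1)))
  out
}

#' Read an atlas pool from a directory
#'
#' Expects the layout written by the pipeline's phantom stage:
#' `<id>_intensity.nii.gz`, `<id>_labels.nii.gz`, `<id>_landmarks.json`.
#'
#' @param dir directory containing atlas files.
#' @return list of [atlas()] objects.
#' @export
read_atlas_pool <- function(dir) {
  if (!dir.exists(dir)) stop("atlas directory not found: ", dir, call. = FALSE)
  ids <- sub("_intensity\\.nii(\\.gz)?$", "",
             basename(list.files(dir, pattern = "_intensity\\.nii(\\.gz)?$")))
  if (length(ids) == 0) stop("no atlases found in ", dir, call. = FALSE)
  lapply(ids, function(id) {
    f <- function(suffix) {
      cand <- file.path(dir, paste0(id, suffix, c(".nii.gz", ".nii", ".json")))
      cand[file.exists(cand)][1]
    }
    atlas(intensity = read_volume(f("_intensity")),
          labels = read_volume(f("_labels")),
          landmarks = read_landmarks(file.path(dir, paste0(id, "_landmarks.json"))),
          atlas_id = id)
  })
}

#' LV volumetry from a label map
#'
#' End-diastolic cavity volume and myocardial mass from voxel counts
#' (myocardial density 1.05 g/mL), indexed to body surface area.
#'
#' @param labels label [volume_image()].
#' @param body_surface_area_m2 BSA in m^2 (> 0).
#' @return one-row tibble: `lvedv_ml`, `lv_mass_g`, `lvedvi_ml_m2`,
#'   `lvmi_g_m2`.
#' @examples
#' lab <- volume_image(array(rep(c(1L, 2L), c(500, 500)), c(10, 10, 10)))
#' compute_volumetry(lab, body_surface_area_m2 = 1.8)
#' @export
compute_volumetry <- function(labels, body_surface_area_m2) {
  stopifnot(inherits(labels, "volume_image"))
  assert_label_volume(labels)
  if (!is.finite(body_surface_area_m2) || body_surface_area_m2 <= 0)
    stop("`body_surface_area_m2` must be > 0", call. = FALSE)
  vv <- voxel_volume(labels)
  n_cav <- sum(labels$data == 1)
  n_myo <- sum(labels$data == 2)
  if (n_myo == 0) stop("empty segmentation: no myocardium voxels", call. = FALSE)
  lvedv_ml <- n_cav * vv / 1000
  mass_g <- n_myo * vv / 1000 * 1.05
  tibble::tibble(lvedv_ml = lvedv_ml,
                 lv_mass_g = mass_g,
                 lvedvi_ml_m2 = lvedv_ml / body_surface_area_m2,
                 lvmi_g_m2 = mass_g / body_surface_area_m2)
}
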