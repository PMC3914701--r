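#' Extract endocardial and epicardial surfaces from a label map
#'
#' Meshes the boundary of the LV cavity (endocardium) and of the
#' cavity-plus-myocardium region (epicardium) by isosurfacing the binary
#' masks at 0.5 (tetrahedral decomposition of the voxel grid), followed by
#' a few Taubin smoothing passes to damp voxelization ripple. Meshes are in
#' physical mm, in the same frame as the volume.
#'
#' @param labels label [volume_image()] (codes 0..3).
#' @param smooth_iterations Taubin passes (0 disables smoothing).
#' @return list with `endo` and `epi` [surface_mesh()]s.
#' @export
extract_surfaces <- function(labels, smooth_iterations = 60) {
  stopifnot(inherits(labels, "volume_image"))
  assert_label_volume(labels)
  if (!any(labels$data == 2))
    stop("no myocardium voxels in the label map", call. = FALSE)
  if (!any(labels$data == 1))
    stop("no LV cavity voxels in the label map", call. = FALSE)
  endo <- isosurface_from_mask(labels$data == 1, labels, "endocardium",
                               smooth_iterations)
  epi <- isosurface_from_mask(labels$data == 1 | labels$data == 2, labels,
                              "epicardium", smooth_iterations)
  for (m in list(endo, epi)) {
    ed <- rbind(m$triangles[, c(1, 2)], m$triangles[, c(2, 3)],
                m$triangles[, c(3, 1)])
    key <- pmin(ed[, 1], ed[, 2]) + (nrow(m$points) + 1) * pmax(ed[, 1], ed[, 2])
    n_edges <- length(unique(key))
    if (nrow(m$points) - n_edges + nrow(m$triangles) != 2L)
      warning("surface is not a closed genus-0 mesh (holes in the myocardium?)",
              call. = FALSE)
  }
  list(endo = endo, epi = epi)
}

isosurface_from_mask <- function(mask, vol, surface, smooth_iterations) {
  d <- dim(mask)
  padded <- array(0, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  res <- march_tetrahedra_cpp(as.numeric(padded), dim(padded), 0.5,
                              vol$spacing, vol$origin - vol$spacing)
  pts <- res$points
  if (smooth_iterations > 0)
    pts <- taubin_smooth_cpp(pts, res$triangles, smooth_iterations, 0.5, -0.53)
  surface_mesh(pts, res$triangles, surface = surface)
}

# resample a volume to a new isotropic/anisotropic spacing over the same
# physical extent
resample_volume <- function(vol, new_spacing, nearest = FALSE) {
  d <- dim(vol$data)
  extent <- (d - 1) * vol$spacing
  nd <- pmax(2L, as.integer(floor(extent / new_spacing)) + 1L)
  ii <- seq_len(nd[1]) - 1; jj <- seq_len(nd[2]) - 1; kk <- seq_len(nd[3]) - 1
  idx_new <- cbind(rep(ii, times = nd[2] * nd[3]),
                   rep(rep(jj, each = nd[1]), times = nd[3]),
                   rep(kk, each = nd[1] * nd[2]))
  world <- sweep(sweep(idx_new, 2, new_spacing, `*`), 2, vol$origin, `+`)
  idx_old <- world_to_voxel(vol, world)
  v <- sample_volume_cpp(as.numeric(vol$data), d, idx_old, nearest = nearest,
                         fill = 0)
  out <- array(if (nearest) as.integer(v) else v, nd)
  volume_image(out, spacing = new_spacing, origin = vol$origin)
}

# iterative closest point with a similarity transform; sources is a list of
# point matrices, targets a parallel list of surface_mesh to project onto
icp_similarity <- function(sources, targets, init, max_iter = 200, tol = 1e-4) {
  cur <- init
  prev_res <- Inf
  src_all <- do.call(rbind, sources)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    moved <- apply_transform(cur, src_all)
    offs <- c(0L, cumsum(vapply(sources, nrow, integer(1))))
    proj <- matrix(0, nrow(src_all), 3)
    for (i in seq_along(sources)) {
      sel <- (offs[i] + 1):offs[i + 1]
      proj[sel, ] <- project_points_cpp(moved[sel, , drop = FALSE],
                                        targets[[i]]$points,
                                        targets[[i]]$triangles)$points
    }
    cur <- fit_similarity(src_all, proj)
    res <- cur$residual_rms
    if (is.finite(prev_res) && abs(prev_res - res) < tol * (1 + res)) {
      converged <- TRUE; prev_res <- res; break
    }
    prev_res <- res
  }
  cur$converged <- converged
  cur$final_residual <- prev_res
  cur
}

#' Build a mean-shape template from an atlas pool
#'
#' Extracts endo/epi surfaces from every atlas, establishes point
#' correspondence by registering the first atlas's surfaces (re-meshed at
#' `template_spacing` to fix the template point count) to each other atlas
#' with a landmark-initialised similarity + ICP projection, and averages the
#' corresponded points in the common frame. Each template endocardial point
#' is paired with an epicardial point along its outward normal, so the
#' endo, epi and midwall meshes share one correspondence index and
#' triangulation; the midwall point count `P` fixes the length of every
#' [thickness_map()].
#'
#' @param atlases list of [atlas()] objects (>= 2).
#' @param template_spacing spacing at which the template geometry is meshed
#'   (controls `P`).
#' @param smooth_iterations Taubin passes for surface extraction.
#' @param base_exclusion_mm template points closer than this to the basal
#'   (mitral) plane — defined by the reference atlas's apex and base-centre
#'   landmarks — are dropped: the flat basal cut of a segmentation is not
#'   myocardial wall.
#' @return object of class `template_model`: `endo`, `epi`, `midwall`
#'   meshes, point count `P`, and the reference landmarks.
#' @export
build_template <- function(atlases, template_spacing = c(2.5, 2.5, 2.5),
                           smooth_iterations = 60, base_exclusion_mm = 4) {
  if (length(atlases) < 2) stop("need at least two atlases", call. = FALSE)
  ref_lab <- resample_volume(atlases[[1]]$labels, template_spacing, nearest = TRUE)
  ref <- extract_surfaces(ref_lab, smooth_iterations)
  pair <- pair_endo_epi(ref$endo, ref$epi)
  endo_pts <- pair$endo; epi_pts <- pair$epi; tri <- ref$endo$triangles

  lm <- unclass(atlases[[1]]$landmarks)
  axis <- lm["base_center", ] - lm["apex", ]
  axis <- axis / sqrt(sum(axis^2))
  proj <- as.numeric(sweep(endo_pts, 2, lm["base_center", ]) %*% axis)
  keep <- which(proj <= -base_exclusion_mm)
  if (length(keep) < 10) stop("basal exclusion removed the whole template",
                              call. = FALSE)
  remap <- match(seq_len(nrow(endo_pts)), keep)
  tri <- matrix(remap[tri], ncol = 3)
  tri <- tri[stats::complete.cases(tri), , drop = FALSE]
  endo_pts <- endo_pts[keep, , drop = FALSE]
  epi_pts <- epi_pts[keep, , drop = FALSE]

  acc_endo <- matrix(0, nrow(endo_pts), 3)
  acc_epi <- matrix(0, nrow(epi_pts), 3)
  for (k in seq_along(atlases)) {
    a <- atlases[[k]]
    surf <- extract_surfaces(a$labels, smooth_iterations)
    init <- fit_similarity(unclass(atlases[[1]]$landmarks), unclass(a$landmarks))
    xf <- icp_similarity(list(endo_pts, epi_pts), list(surf$endo, surf$epi), init)
    if (!xf$converged)
      stop("template registration failed on atlas ", a$atlas_id,
           " (residual ", signif(xf$final_residual, 4), " mm)", call. = FALSE)
    cor_endo <- project_points_cpp(apply_transform(xf, endo_pts),
                                   surf$endo$points, surf$endo$triangles)$points
    cor_epi <- project_points_cpp(apply_transform(xf, epi_pts),
                                  surf$epi$points, surf$epi$triangles)$points
    inv <- invert_transform(xf)
    acc_endo <- acc_endo + apply_transform(inv, cor_endo)
    acc_epi <- acc_epi + apply_transform(inv, cor_epi)
  }
  endo_mean <- acc_endo / length(atlases)
  epi_mean <- acc_epi / length(atlases)
  mid <- (endo_mean + epi_mean) / 2
  structure(list(endo = surface_mesh(endo_mean, tri, "endocardium"),
                 epi = surface_mesh(epi_mean, tri, "epicardium"),
                 midwall = surface_mesh(mid, tri, "midwall"),
                 P = nrow(endo_mean),
                 landmarks = atlases[[1]]$landmarks),
            class = "template_model")
}

#' @export
print.template_model <- function(x, ...) {
  cat("<template_model> P =", x$P, "correspondence points\n")
  invisible(x)
}

# pair each endo vertex with the epi intersection along its outward normal
# (nearest-point fallback when the ray misses)
pair_endo_epi <- function(endo, epi) {
  nrm <- vertex_normals_cpp(endo$points, endo$triangles)
  nrm <- taubin_smooth_cpp(nrm, endo$triangles, 10, 0.5, 0)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  hit <- line_mesh_intersect_cpp(endo$points, nrm, epi$points, epi$triangles)
  pts <- hit$point
  miss <- !is.finite(hit$t) |
    abs(hit$t) > 3 * stats::median(abs(hit$t), na.rm = TRUE)
  if (any(miss)) {
    pr <- project_points_cpp(endo$points[miss, , drop = FALSE],
                             epi$points, epi$triangles)
    pts[miss, ] <- pr$points
  }
  list(endo = endo$points, epi = pts)
}

#' Register the template to a target's surfaces
#'
#' Similarity alignment (landmark-based when landmarks are supplied,
#' centroid/scale moments otherwise) refined by iterative closest point,
#' then projection of every template point onto the target surface. The
#' output meshes carry the template's point count and triangulation, so
#' point `k` is anatomically consistent across subjects.
#'
#' @param template a [template_model()][build_template].
#' @param target_endo,target_epi target [surface_mesh()]s (e.g. from
#'   [extract_surfaces()]).
#' @param target_landmarks optional [landmark_set()] for initialisation.
#' @param max_iter,tol ICP controls.
#' @return list with corresponded `endo` and `epi` meshes, the fitted
#'   `transform` and the final ICP `residual_rms`.
#' @export
register_template <- function(template, target_endo, target_epi,
                              target_landmarks = NULL, max_iter = 200,
                              tol = 1e-4) {
  stopifnot(inherits(template, "template_model"))
  if (!is.null(target_landmarks)) {
    init <- fit_similarity(unclass(template$landmarks), unclass(target_landmarks))
  } else {
    src <- rbind(template$endo$points, template$epi$points)
    tgt <- rbind(target_endo$points, target_epi$points)
    sc <- sqrt(mean(rowSums(sweep(tgt, 2, colMeans(tgt))^2)) /
                 mean(rowSums(sweep(src, 2, colMeans(src))^2)))
    init <- structure(list(rotation = diag(3), scale = sc,
                           translation = colMeans(tgt) - sc * colMeans(src),
                           residual_rms = NA_real_),
                      class = "similarity_transform")
  }
  xf <- icp_similarity(list(template$endo$points, template$epi$points),
                       list(target_endo, target_epi), init,
                       max_iter = max_iter, tol = tol)
  if (!xf$converged)
    stop("ICP did not converge after ", max_iter, " iterations (residual ",
         signif(xf$final_residual, 4), " mm)", call. = FALSE)
  cor_endo <- project_points_cpp(apply_transform(xf, template$endo$points),
                                 target_endo$points, target_endo$triangles)$points
  cor_epi <- project_points_cpp(apply_transform(xf, template$epi$points),
                                target_epi$points, target_epi$triangles)$points
  list(endo = surface_mesh(cor_endo, template$endo$triangles, "endocardium"),
       epi = surface_mesh(cor_epi, template$endo$triangles, "epicardium"),
       transform = xf, residual_rms = xf$final_residual)
}

#' Measure wall thickness at template correspondence points
#'
#' The midwall point is the endo/epi midpoint; thickness is measured along
#' the midwall surface normal as the distance between the intersections of
#' that normal line with the endocardial and epicardial surfaces. When a
#' normal ray misses a surface (or yields an implausible crossing), the
#' Euclidean endo-epi point distance is used instead; the number of
#' fallbacks is recorded in the `n_fallback` attribute.
#'
#' @param endo,epi corresponded meshes from [register_template()] (equal
#'   point counts, shared triangulation).
#' @param subject_id,acquisition_id identifiers carried into the result.
#' @return a [thickness_map()] of length `P`.
#' @export
measure_thickness <- function(endo, epi, subject_id = NA_character_,
                              acquisition_id = NA_character_) {
  stopifnot(inherits(endo, "surface_mesh"), inherits(epi, "surface_mesh"))
  if (nrow(endo$points) != nrow(epi$points))
    stop("corresponded meshes must share the template point count", call. = FALSE)
  mid <- (endo$points + epi$points) / 2
  nrm <- vertex_normals_cpp(mid, endo$triangles)
  # relax the normal field over the mesh neighbourhood before ray casting;
  # projection-induced triangle irregularity otherwise produces oblique rays
  nrm <- taubin_smooth_cpp(nrm, endo$triangles, 10, 0.5, 0)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  direct <- sqrt(rowSums((epi$points - endo$points)^2))
  he <- line_mesh_intersect_cpp(mid, nrm, endo$points, endo$triangles)
  hp <- line_mesh_intersect_cpp(mid, nrm, epi$points, epi$triangles)
  th <- abs(hp$t - he$t)
  bad <- !is.finite(th) | th <= 0 | abs(th - direct) > pmax(2, 0.5 * direct)
  th[bad] <- direct[bad]
  out <- thickness_map(th, subject_id = subject_id,
                       acquisition_id = acquisition_id)
  attr(out, "n_fallback") <- sum(bad)
  out
}
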