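#' Dice similarity coefficient
#'
#' Overlap between two label maps for one structure:
#' `2|A n B| / (|A| + |B|)`; 0 is no overlap, 1 perfect agreement. Defined
#' as 1 when both sets are empty (vacuous agreement) and 0 when exactly one
#' is empty.
#'
#' @param labels_a,labels_b label [volume_image()]s on the same grid.
#' @param label_code structure code (1 LV cavity, 2 myocardium, ...).
#' @return scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(labels_a, labels_b, label_code) {
  stopifnot(inherits(labels_a, "volume_image"), inherits(labels_b, "volume_image"))
  if (!identical(dim(labels_a$data), dim(labels_b$data)))
    stop("label volumes are on different grids", call. = FALSE)
  A <- labels_a$data == label_code
  B <- labels_b$data == label_code
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) return(1)
  2 * sum(A & B) / (na + nb)
}

#' Point-to-surface / corresponded point distances
#'
#' In `"corresponded"` mode, distances between identically indexed points of
#' two corresponded meshes; in `"nearest"` mode, the distance from each
#' point of `mesh` to the closest point on the `reference` surface.
#'
#' @param mesh,reference [surface_mesh()]s.
#' @param mode `"corresponded"` (default, requires equal point counts) or
#'   `"nearest"`.
#' @return list with `mean_mm`, `sd_mm` and the per-point `distances`.
#' @export
surface_distance <- function(mesh, reference,
                             mode = c("corresponded", "nearest")) {
  mode <- match.arg(mode)
  if (mode == "corresponded") {
    if (nrow(mesh$points) != nrow(reference$points))
      stop("corresponded mode requires equal point counts", call. = FALSE)
    d <- sqrt(rowSums((mesh$points - reference$points)^2))
  } else {
    d <- project_points_cpp(mesh$points, reference$points,
                            reference$triangles)$distance
  }
  list(mean_mm = mean(d), sd_mm = sd(d), distances = d)
}

#' Contrast ratio between two image regions
#'
#' `CR = (SI1 - SI2) / sqrt(SD1^2 + SD2^2)` from the means and SDs of two
#' relatively homogeneous regions (blood pool and myocardium in cardiac
#' cine imaging). The sign follows `SI1 - SI2`; take the absolute value for
#' blood-vs-myocardium reporting.
#'
#' @param region1_intensities,region2_intensities numeric vectors of voxel
#'   intensities (non-empty).
#' @return scalar CR.
#' @examples
#' contrast_ratio(rnorm(100, 100, 5), rnorm(100, 50, 5))  # about 7
#' @export
contrast_ratio <- function(region1_intensities, region2_intensities) {
  if (length(region1_intensities) == 0 || length(region2_intensities) == 0)
    stop("both regions must be non-empty", call. = FALSE)
  s1 <- sd(region1_intensities); s2 <- sd(region2_intensities)
  if (length(region1_intensities) == 1) s1 <- 0
  if (length(region2_intensities) == 1) s2 <- 0
  pooled <- sqrt(s1^2 + s2^2)
  if (!is.finite(pooled) || pooled == 0)
    stop("undefined contrast ratio: zero pooled SD", call. = FALSE)
  (mean(region1_intensities) - mean(region2_intensities)) / pooled
}

#' Leave-one-out segmentation accuracy over an atlas pool
#'
#' Each atlas is segmented using the remaining atlases and scored against
#' its own labels: Dice per structure, and optionally nearest-point surface
#' distances for the endo- and epicardium. With `emulate_2d = TRUE`, the
#' target intensity volume is pooled into a thick-slice stack before
#' segmentation and the reference labels are down-sampled to the same
#' resolution, so the comparison to the thin-slice arm is unbiased.
#'
#' @param atlases list of [atlas()] objects (>= 2).
#' @param params a [fusion_params()].
#' @param emulate_2d segment a thick-slice emulation instead of the native
#'   volume.
#' @param slice_thickness_mm,gap_mm stack geometry for the 2D arm.
#' @param compute_distances also extract surfaces and score point-to-surface
#'   distances (slower).
#' @param n_atlases_use optionally segment with only the first `n` of the
#'   remaining atlases (used for accuracy-vs-pool-size sweeps).
#' @return tibble with one row per atlas: Dice for cavity and myocardium,
#'   and (if requested) mean/SD endo- and epicardial distances in mm.
#' @export
leave_one_out_accuracy <- function(atlases, params = fusion_params(),
                                   emulate_2d = FALSE,
                                   slice_thickness_mm = 8, gap_mm = 2,
                                   compute_distances = FALSE,
                                   n_atlases_use = NULL) {
  if (length(atlases) < 2) stop("need at least two atlases", call. = FALSE)
  rows <- lapply(seq_along(atlases), function(i) {
    tgt <- atlases[[i]]
    pool <- atlases[-i]
    if (!is.null(n_atlases_use)) pool <- pool[seq_len(min(n_atlases_use, length(pool)))]
    if (emulate_2d) {
      target_gray <- resample_to_stack(tgt$intensity, slice_thickness_mm,
                                       gap_mm, kind = "grayscale")
      ref_labels <- resample_to_stack(tgt$labels, slice_thickness_mm,
                                      gap_mm, kind = "labels")
    } else {
      target_gray <- tgt$intensity
      ref_labels <- tgt$labels
    }
    seg <- fuse_labels(target_gray, pool, params, target_landmarks = tgt$landmarks)
    out <- tibble::tibble(
      atlas_id = tgt$atlas_id,
      arm = if (emulate_2d) "2D" else "3D",
      n_atlases = length(pool),
      dice_lv_cavity = dice_coefficient(seg, ref_labels, 1L),
      dice_myocardium = dice_coefficient(seg, ref_labels, 2L))
    if (compute_distances) {
      sseg <- extract_surfaces(seg)
      sref <- extract_surfaces(ref_labels)
      de <- surface_distance(sseg$endo, sref$endo, mode = "nearest")
      dp <- surface_distance(sseg$epi, sref$epi, mode = "nearest")
      out$endo_dist_mean_mm <- de$mean_mm
      out$endo_dist_sd_mm <- de$sd_mm
      out$epi_dist_mean_mm <- dp$mean_mm
      out$epi_dist_sd_mm <- dp$sd_mm
    }
    out
  })
  dplyr::bind_rows(rows)
}
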