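#' 3D image volume with physical geometry
#'
#' A `volume_image` is the package's container for a scalar 3D grid: a data
#' array plus per-axis voxel spacing and a physical origin, all in mm.
#' The physical coordinate of voxel index `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing` (voxel-centre convention). The same
#' container carries both grayscale intensities and integer label maps;
#' label maps use the codes 0 (background), 1 (LV cavity), 2 (myocardium)
#' and 3 (RV cavity).
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm (all > 0).
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @return An object of class `volume_image`.
#' @examples
#' vol <- volume_image(array(0, c(4, 4, 4)), spacing = c(1.2, 1.2, 2))
#' voxel_volume(vol)
#' @export
volume_image <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 4), collapse = ", "),
      ") mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' @export
dim.volume_image <- function(x) dim(x$data)

# labels valid for myocardial segmentations
LABEL_CODES <- c(background = 0L, lv_cavity = 1L, myocardium = 2L, rv_cavity = 3L)

is_label_data <- function(data) {
  all(data == round(data)) && all(data %in% 0:3)
}

assert_label_volume <- function(vol) {
  if (!is_label_data(vol$data))
    stop("label volume must contain only codes 0..3", call. = FALSE)
  invisible(vol)
}

#' Physical volume of one voxel in mm^3
#' @param image a [volume_image()].
#' @return scalar, mm^3.
#' @export
voxel_volume <- function(image) prod(image$spacing)

#' Convert between voxel indices and physical coordinates
#'
#' Indices are 0-based, following the voxel-centre convention
#' `world = origin + index * spacing`.
#'
#' @param image a [volume_image()].
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of physical mm coordinates.
#' @export
voxel_to_world <- function(image, idx) {
  idx <- rbind(idx)
  sweep(sweep(idx, 2, image$spacing, `*`), 2, image$origin, `+`)
}

#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of physical mm coordinates.
#' @export
world_to_voxel <- function(image, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, image$origin, `-`), 2, image$spacing, `/`)
}

#' Read a NIfTI-1 volume
#'
#' Spacing and origin are taken from the NIfTI transform (sform/qform);
#' only 3D payloads are accepted.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume_image()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) { dim(img) <- d[1:3]; d <- d[1:3] }
  if (length(d) != 3L)
    stop("expected a 3D volume, got ", length(d), " dimensions", call. = FALSE)
  m <- RNifti::xform(img)
  spacing <- sqrt(colSums(m[1:3, 1:3]^2))
  origin <- m[1:3, 4]
  # RNifti's xform is RAS-ish; the package convention is axis-aligned grids,
  # so reduce to the per-axis scale (all phantom/pipeline volumes are
  # axis-aligned by construction).
  volume_image(array(as.numeric(img), dim = d), spacing = spacing, origin = origin)
}

#' Write a NIfTI-1 volume
#'
#' Round-trips with [read_volume()]: data, spacing and origin are preserved
#' (labels bit-exactly, grayscale to float precision).
#'
#' @param image a [volume_image()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "volume_image"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  img <- RNifti::asNifti(image$data)
  img <- RNifti::`pixdim<-`(img, image$spacing)
  m <- diag(c(image$spacing, 1))
  m[1:3, 4] <- image$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  ok <- tryCatch({ RNifti::writeNifti(img, path); TRUE },
                 error = function(e) FALSE)
  if (!ok || !file.exists(path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

#' Emulate a thick-slice 2D multi-slice acquisition
#'
#' Pools the z-axis of a thin-slice volume into slabs, as in a conventional
#' short-axis cine stack (e.g. 8 mm sections with a 2 mm gap): each output
#' slice is the slab average for grayscale data or the slab majority label
#' (ties toward the lower code) for label maps. Slab windows are half-open
#' and start at the physical edge of the first voxel; the output z-spacing is
#' `slice_thickness_mm + gap_mm`. A final slab that extends past the volume
#' is truncated and flagged with a warning.
#'
#' @param image a [volume_image()].
#' @param slice_thickness_mm slab (section) thickness in mm, > 0.
#' @param gap_mm inter-section gap in mm, >= 0.
#' @param kind `"auto"` (detect label maps), `"grayscale"` or `"labels"`.
#' @return a [volume_image()] with coarse z-sampling.
#' @examples
#' vol <- volume_image(array(rnorm(16 * 16 * 20), c(16, 16, 20)),
#'                     spacing = c(1.2, 1.2, 2))
#' stack <- resample_to_stack(vol, slice_thickness_mm = 8, gap_mm = 2)
#' stack$spacing  # z becomes 10 mm
#' @export
resample_to_stack <- function(image, slice_thickness_mm, gap_mm = 0,
                              kind = c("auto", "grayscale", "labels")) {
  stopifnot(inherits(image, "volume_image"))
  kind <- match.arg(kind)
  if (!is.finite(slice_thickness_mm) || slice_thickness_mm <= 0)
    stop("`slice_thickness_mm` must be > 0", call. = FALSE)
  if (!is.finite(gap_mm) || gap_mm < 0)
    stop("`gap_mm` must be >= 0", call. = FALSE)
  dz <- image$spacing[3]
  nz <- dim(image$data)[3]
  z_extent <- nz * dz
  if (z_extent < slice_thickness_mm && nz > 1)
    stop("volume z-extent smaller than one slab", call. = FALSE)
  if (kind == "auto")
    kind <- if (is_label_data(image$data)) "labels" else "grayscale"

  z0_edge <- image$origin[3] - dz / 2     # physical edge of first voxel
  zc <- image$origin[3] + (seq_len(nz) - 1) * dz
  pitch <- slice_thickness_mm + gap_mm
  n_out <- max(1L, floor((z_extent - slice_thickness_mm) / pitch + 1e-9) + 1L)
  # a trailing partial slab is kept (truncated) if it still covers voxels
  truncated <- FALSE
  if (z0_edge + n_out * pitch < z0_edge + z_extent - 1e-9) {
    extra_start <- z0_edge + n_out * pitch
    if (any(zc >= extra_start - 1e-9)) { n_out <- n_out + 1L; truncated <- TRUE }
  }
  d <- dim(image$data)
  out <- array(0, c(d[1], d[2], n_out))
  for (s in seq_len(n_out)) {
    w0 <- z0_edge + (s - 1) * pitch
    sel <- which(zc >= w0 - 1e-9 & zc < w0 + slice_thickness_mm - 1e-9)
    if (length(sel) == 0L) { n_out <- s - 1L; out <- out[, , seq_len(n_out), drop = FALSE]; break }
    slab <- image$data[, , sel, drop = FALSE]
    if (kind == "grayscale") {
      out[, , s] <- apply(slab, c(1, 2), mean)
    } else {
      counts <- vapply(0:3, function(code) rowSums(slab == code, dims = 2),
                       matrix(0, d[1], d[2]))
      out[, , s] <- max.col(matrix(counts, ncol = 4), ties.method = "first") - 1L
    }
  }
  if (truncated)
    warning("final slab truncated at the volume boundary", call. = FALSE)
  new_origin <- image$origin
  new_origin[3] <- z0_edge + slice_thickness_mm / 2
  volume_image(out, spacing = c(image$spacing[1:2], pitch),
               origin = c(image$origin[1:2], new_origin[3]))
}
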