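#' Triangulated surface mesh
#'
#' Points are in physical mm (the same frame as [volume_image()] volumes);
#' triangles are 1-based index triplets. When a mesh has been put into
#' template correspondence, point `k` denotes the same anatomical location on
#' every subject's mesh.
#'
#' @param points P x 3 numeric matrix, mm.
#' @param triangles T x 3 integer matrix of 1-based point indices.
#' @param surface one of `"endocardium"`, `"epicardium"`, `"midwall"`.
#' @return an object of class `surface_mesh`.
#' @export
surface_mesh <- function(points, triangles,
                         surface = c("endocardium", "epicardium", "midwall")) {
  surface <- match.arg(surface)
  points <- as.matrix(points)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(points) != 3L) stop("`points` must be P x 3", call. = FALSE)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(points)))
    stop("triangle indices out of range", call. = FALSE)
  structure(list(points = points, triangles = triangles, surface = surface),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", x$surface, ": ", nrow(x$points), " points, ",
      nrow(x$triangles), " triangles\n", sep = "")
  invisible(x)
}

#' Total surface area of a mesh in mm^2
#' @param mesh a [surface_mesh()].
#' @export
mesh_area <- function(mesh) {
  P <- mesh$points; Tm <- mesh$triangles
  a <- P[Tm[, 2], , drop = FALSE] - P[Tm[, 1], , drop = FALSE]
  b <- P[Tm[, 3], , drop = FALSE] - P[Tm[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Outward vertex normals (area-weighted, from triangle winding)
#' @param mesh a [surface_mesh()].
#' @return P x 3 matrix of unit normals.
#' @export
mesh_vertex_normals <- function(mesh) {
  vertex_normals_cpp(mesh$points, mesh$triangles)
}

#' Read / write meshes as ASCII PLY
#'
#' @param path `.ply` file path.
#' @param surface surface tag to attach on read.
#' @return [read_ply()] returns a [surface_mesh()].
#' @export
read_ply <- function(path, surface = "endocardium") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != "ply")
    stop("not a PLY file: ", path, call. = FALSE)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("malformed PLY header", call. = FALSE)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "", grep("^element face ", lines, value = TRUE)[1]))
  vtx <- do.call(rbind, lapply(lines[hdr_end + seq_len(nv)],
                               function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
  fc <- do.call(rbind, lapply(lines[hdr_end + nv + seq_len(nf)], function(l) {
    v <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
    if (v[1] != 3L) stop("only triangle faces supported", call. = FALSE)
    v[2:4] + 1L
  }))
  surface_mesh(vtx, fc, surface = surface)
}

#' @rdname read_ply
#' @param mesh a [surface_mesh()].
#' @param scalars optional per-point numeric vector written as a `quality`
#'   property (used for thickness / sample-size renderings).
#' @export
write_ply <- function(mesh, path, scalars = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  nv <- nrow(mesh$points); nf <- nrow(mesh$triangles)
  props <- c("property float x", "property float y", "property float z")
  if (!is.null(scalars)) {
    stopifnot(length(scalars) == nv)
    props <- c(props, "property float quality")
  }
  hdr <- c("ply", "format ascii 1.0",
           paste("element vertex", nv), props,
           paste("element face", nf),
           "property list uchar int vertex_indices", "end_header")
  vtx <- mesh$points
  vl <- if (is.null(scalars)) {
    sprintf("%.6f %.6f %.6f", vtx[, 1], vtx[, 2], vtx[, 3])
  } else {
    sprintf("%.6f %.6f %.6f %.6f", vtx[, 1], vtx[, 2], vtx[, 3], scalars)
  }
  fl <- sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}

#' Per-point wall-thickness map
#'
#' Wall thickness in mm at each midwall correspondence point of one
#' subject/acquisition; the length equals the template midwall point count.
#'
#' @param values numeric vector of thicknesses (mm).
#' @param subject_id,acquisition_id identifiers.
#' @return object of class `thickness_map`.
#' @export
thickness_map <- function(values, subject_id = NA_character_,
                          acquisition_id = NA_character_) {
  values <- as.numeric(values)
  structure(list(values = values, subject_id = subject_id,
                 acquisition_id = acquisition_id),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat("<thickness_map> ", length(x$values), " points, mean ",
      round(mean(x$values, na.rm = TRUE), 2), " mm (subject ",
      x$subject_id, ", acquisition ", x$acquisition_id, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.thickness_map <- function(x, ...) {
  tibble::tibble(point_index = seq_along(x$values),
                 thickness_mm = x$values,
                 subject_id = x$subject_id,
                 acquisition_id = x$acquisition_id)
}

#' @export
autoplot.thickness_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$thickness_mm)) +
    ggplot2::geom_histogram(bins = 40, fill = "firebrick", colour = "white") +
    ggplot2::labs(x = "wall thickness (mm)", y = "points",
                  title = paste0("Wall thickness, subject ", object$subject_id))
}

#' Read / write per-point tables (CSV)
#'
#' Column layout `point_index,value`, the exchange format for thickness and
#' sample-size maps.
#' @param path CSV path.
#' @export
read_point_table <- function(path) {
  tibble::as_tibble(read.csv(path))
}

#' @rdname read_point_table
#' @param values per-point numeric vector.
#' @export
write_point_table <- function(values, path) {
  write.csv(data.frame(point_index = seq_along(values), value = values),
            path, row.names = FALSE)
  invisible(path)
}
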