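#' Anatomical landmark set
#'
#' Six named 3D points, in mm, used to initialise atlas-to-target alignment:
#' the apex, the centre of the mitral annulus (base), the lateral and septal
#' mitral annulus points, and the anterior and inferior right-ventricular
#' insertion points. The naming is a package convention; any six distinct,
#' consistently named points work.
#'
#' @param points a 6 x 3 numeric matrix with rownames, or a named list of
#'   length-3 numeric vectors.
#' @return an object of class `landmark_set` (6 x 3 matrix, mm).
#' @export
landmark_set <- function(points) {
  if (is.list(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, as.numeric))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (nrow(points) != 6L || ncol(points) != 3L)
    stop("a landmark set has exactly six 3D points", call. = FALSE)
  if (is.null(rownames(points)) || anyDuplicated(rownames(points)))
    stop("landmarks must have unique names", call. = FALSE)
  if (any(!is.finite(points)))
    stop("landmark coordinates must be finite", call. = FALSE)
  if (anyDuplicated(round(points, 9)))
    stop("landmarks must be pairwise distinct", call. = FALSE)
  structure(points, class = c("landmark_set", "matrix", "array"))
}

landmark_names <- c("apex", "base_center", "mitral_lateral", "mitral_septal",
                    "rv_insertion_anterior", "rv_insertion_inferior")

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> (mm)\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Read / write landmarks as JSON
#'
#' The on-disk format is a JSON object `{name: [x, y, z], ...}` in mm.
#'
#' @param path JSON file path.
#' @return [read_landmarks()] returns a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  landmark_set(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_landmarks
#' @param landmarks a [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- lapply(seq_len(nrow(landmarks)), function(i) as.numeric(landmarks[i, ]))
  names(obj) <- rownames(landmarks)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}
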