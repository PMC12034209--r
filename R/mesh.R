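#' Triangle mesh container
#'
#' A minimal triangle-mesh container in the style of ape's `phylo`: a list
#' with an `n x 3` numeric `vertices` matrix (coordinates in mm), an
#' `m x 3` integer `faces` matrix of 1-based vertex indices, and an optional
#' `specimen_id`.  Every stage of the pipeline consumes and produces this
#' class.
#'
#' @param vertices Numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces Integer matrix, one row per triangle, 1-based vertex indices.
#' @param specimen_id Optional specimen identifier string.
#' @return An object of class `mesh3t`.
#' @export
mesh3t <- function(vertices, faces, specimen_id = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) > 0L) {
    if (min(faces) < 1L || max(faces) > nrow(vertices))
      stop_morpho("face index out of range", "index_range")
    if (any(faces[, 1] == faces[, 2] | faces[, 1] == faces[, 3] |
              faces[, 2] == faces[, 3]))
      stop("a face repeats a vertex")
  }
  dimnames(vertices) <- list(NULL, c("x", "y", "z"))
  dimnames(faces) <- NULL
  structure(list(vertices = vertices, faces = faces,
                 specimen_id = specimen_id), class = "mesh3t")
}

#' @export
print.mesh3t <- function(x, ...) {
  cat(sprintf("<mesh3t> %s: %d vertices, %d faces, %s\n",
              x$specimen_id %||% "(unnamed)", nrow(x$vertices), nrow(x$faces),
              if (is_watertight(x)) "watertight" else "open"))
  invisible(x)
}

stop_morpho <- function(msg, subclass, ...) {
  rlang::abort(msg, class = paste0("morphoatlas_error_", subclass), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Undirected edge table: one row per face half-edge, columns are the sorted
# endpoint indices.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2), drop = FALSE], f[, c(2, 3), drop = FALSE],
             f[, c(3, 1), drop = FALSE])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

edge_multiplicity <- function(mesh) {
  e <- mesh_edges(mesh)
  table(paste(e[, 1], e[, 2]))
}

#' Watertightness and Euler characteristic
#'
#' A mesh is watertight when every undirected edge is shared by exactly two
#' faces.  The Euler characteristic V - E + F counts only vertices referenced
#' by at least one face, so removing a patch of faces (leaving stranded
#' vertices) is detected as a topology change.
#'
#' @param mesh A [mesh3t()].
#' @return `is_watertight()`: logical. `euler_characteristic()`: integer.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(FALSE)
  all(edge_multiplicity(mesh) == 2L)
}

#' @rdname is_watertight
#' @export
euler_characteristic <- function(mesh) {
  v <- length(unique(as.vector(mesh$faces)))
  e <- length(edge_multiplicity(mesh))
  v - e + nrow(mesh$faces)
}

#' Oriented face measures of a mesh
#'
#' Computes per-face centres c_p = (v1 + v2 + v3)/3 and area-weighted normals
#' n_p = (v2 - v1) x (v3 - v1) / 2, the oriented measures the current and
#' varifold attachment terms are built from.  The normal's magnitude is the
#' face area (mm^2); its direction follows the winding.  Degenerate
#' (zero-area) faces yield a zero normal and a classed warning, not an error.
#'
#' @param mesh A [mesh3t()].
#' @return List with `centres` and `normals`, both `m x 3` matrices.
#' @export
oriented_face_set <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  centres <- (v1 + v2 + v3) / 3
  e1 <- v2 - v1
  e2 <- v3 - v1
  normals <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                   e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                   e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]) / 2
  areas <- sqrt(rowSums(normals^2))
  if (any(areas == 0))
    rlang::warn(sprintf("%d degenerate zero-area face(s)", sum(areas == 0)),
                class = "morphoatlas_warning_degenerate_face")
  list(centres = centres, normals = normals)
}

# Area-weighted vertex normals (sum of incident face normals, normalised).
vertex_normals <- function(mesh) {
  ofs <- oriented_face_set(mesh)
  vn <- matrix(0, nrow(mesh$vertices), 3)
  for (k in 1:3) {
    idx <- mesh$faces[, k]
    for (d in 1:3) vn[, d] <- vn[, d] + tapply_add(ofs$normals[, d], idx,
                                                   nrow(vn))
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tapply_add <- function(values, index, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg
  out
}

mesh_bbox <- function(mesh) {
  rbind(lo = apply(mesh$vertices, 2, min), hi = apply(mesh$vertices, 2, max))
}

#' Distance from points to a triangulated surface
#'
#' Minimum Euclidean distance from each query point to the surface of `mesh`
#' (exact point-to-triangle, brute force over faces).
#'
#' @param points `n x 3` matrix of query points.
#' @param mesh A [mesh3t()].
#' @return Numeric vector of length `n`.
#' @export
point_surface_distance <- function(points, mesh) {
  points <- matrix(as.numeric(points), ncol = 3)
  cpp_point_surface_dist(points, mesh$vertices, mesh$faces)
}

# Symmetric Hausdorff estimate between surfaces via vertex + face-centre
# samples of each against the full other surface.
hausdorff_distance <- function(a, b) {
  ra <- unique(as.vector(a$faces))
  rb <- unique(as.vector(b$faces))
  sa <- rbind(a$vertices[ra, , drop = FALSE],
              suppressWarnings(oriented_face_set(a))$centres)
  sb <- rbind(b$vertices[rb, , drop = FALSE],
              suppressWarnings(oriented_face_set(b))$centres)
  max(max(cpp_point_surface_dist(sa, b$vertices, b$faces)),
      max(cpp_point_surface_dist(sb, a$vertices, a$faces)))
}
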