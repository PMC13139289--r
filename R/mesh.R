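#' Triangle-mesh surface models
#'
#' A `triangle_mesh` stores vertices in world mm and oriented triangular
#' faces (1-based index triples).  Meshes built from a mask by
#' [build_surface()] are watertight (every edge borders exactly two faces)
#' with outward-pointing face normals.
#'
#' @param vertices numeric matrix, one vertex per row (x, y, z in mm).
#' @param faces integer matrix, one face per row (three vertex indices),
#'   wound counter-clockwise when seen from outside.
#' @return a `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || ncol(faces) != 3L)
    stop("vertices and faces must have 3 columns", call. = FALSE)
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces, area %.4g mm^2\n",
              nrow(x$vertices), nrow(x$faces), surface_area(x)))
  invisible(x)
}

#' Build a surface model from a binary mask
#'
#' Extracts the iso-surface of the mask's indicator field at level 0.5
#' using marching tetrahedra on the Kuhn cell decomposition, which yields
#' a watertight, consistently outward-oriented triangle mesh in world mm.
#'
#' Before extraction the \{0,1\} field is anti-aliased with a small
#' Gaussian filter (`sigma`, in voxels).  This sub-voxel filter removes
#' the voxelisation staircase so that the measured surface area converges
#' to the true area under grid refinement; without it the staircase
#' inflates the area of smooth objects by a resolution-independent ~9%.
#' No smoothing is applied to the mesh itself.  Set `sigma = 0` for the
#' raw binary iso-surface.
#'
#' @param mask a non-empty [binary_mask].
#' @param sigma anti-aliasing filter width in voxels (default 0.8).
#' @return a `triangle_mesh` in world mm.
#' @examples
#' m <- binary_mask(array(1L, c(1, 1, 1)), spacing = c(1, 1, 1))
#' build_surface(m)
#' @export
build_surface <- function(mask, sigma = 0.8) {
  stopifnot(inherits(mask, "binary_mask"))
  if (sum(mask$data) == 0L)
    stop("no surface: mask is empty", call. = FALSE)
  pad <- max(2L, as.integer(ceiling(3.5 * sigma)) + 1L)
  d <- dim(mask$data)
  field <- array(0, d + 2L * pad)
  field[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <-
    as.numeric(mask$data)
  raw <- field
  if (sigma > 0) field <- .gaussian_filter3d(field, dim(field), sigma)
  origin <- mask$origin - pad * mask$spacing
  res <- .marching_tetrahedra(field, dim(field), 0.5, mask$spacing, origin)
  if (nrow(res$faces) == 0L && sigma > 0) {
    # deposits near the voxel scale can fall below the iso-level after
    # anti-aliasing; fall back to the raw binary iso-surface for them
    res <- .marching_tetrahedra(raw, dim(raw), 0.5, mask$spacing, origin)
  }
  triangle_mesh(res$vertices, res$faces)
}

mesh_edges_vec <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Watertightness check
#'
#' A closed surface has every undirected edge shared by exactly two faces.
#'
#' @param mesh a [triangle_mesh].
#' @return `TRUE` if closed, else `FALSE`.
#' @export
is_watertight <- function(mesh) {
  e <- mesh_edges_vec(mesh)
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

face_cross <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  p0 <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - p0
  w <- v[f[, 3], , drop = FALSE] - p0
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Per-face geometry
#'
#' `face_normals()` returns unit outward normals (one row per face);
#' `face_areas()` the triangle areas (half cross-product magnitude);
#' `face_centroids()` the vertex means; `surface_area()` the total area
#' S in mm^2, the sum of all face areas.
#'
#' @param mesh a [triangle_mesh].
#' @return matrix (normals, centroids) or numeric vector (areas, area).
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  n <- sqrt(rowSums(cr^2))
  if (any(n == 0)) {
    stop("degenerate (zero-area) face at index ",
         which(n == 0)[1], call. = FALSE)
  }
  cr / n
}

#' @rdname face_normals
#' @export
face_areas <- function(mesh) {
  0.5 * sqrt(rowSums(face_cross(mesh)^2))
}

#' @rdname face_normals
#' @export
face_centroids <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
     v[f[, 3], , drop = FALSE]) / 3
}

#' @rdname face_normals
#' @export
surface_area <- function(mesh) sum(face_areas(mesh))

#' Export meshes for inspection
#'
#' Writes ASCII PLY or STL files readable by standard mesh viewers.
#'
#' @param mesh a [triangle_mesh].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
  writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
write_stl <- function(mesh, path) {
  n <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid calcmorph", con)
  for (i in seq_len(nrow(f))) {
    writeLines(sprintf("facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]), con)
    writeLines("  outer loop", con)
    for (j in 1:3)
      writeLines(sprintf("    vertex %g %g %g",
                         v[f[i, j], 1], v[f[i, j], 2], v[f[i, j], 3]), con)
    writeLines(c("  endloop", "endfacet"), con)
  }
  writeLines("endsolid calcmorph", con)
  invisible(path)
}
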