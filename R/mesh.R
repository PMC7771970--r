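#' Triangulated surface mesh in physical coordinates
#'
#' The geometric substrate of every measurement in the package: a
#' triangulated epidermal surface with vertices in micrometres. Vertex
#' normals are computed (area-weighted average of incident triangle normals)
#' unless supplied, and are oriented so that their mean points along +z,
#' the apex axis for top-down imaged meristems.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates (µm).
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @param normals optional n x 3 matrix of unit vertex normals.
#' @param area_tol triangles with area below this (µm²) are rejected.
#' @return An object of class `surface_mesh`: a list with elements
#'   `vertices`, `triangles`, `normals`.
#' @export
surface_mesh <- function(vertices, triangles, normals = NULL, area_tol = 1e-9) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  dimnames(triangles) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (!all(is.finite(vertices))) stop("non-finite vertex coordinates")
  nv <- nrow(vertices)
  if (any(triangles < 1L) || any(triangles > nv))
    stop("triangle indices out of range")
  a <- triangle_areas_(vertices, triangles)
  if (any(a <= area_tol))
    stop(sum(a <= area_tol), " degenerate (near-zero-area) triangle(s)")
  mesh <- structure(list(vertices = vertices, triangles = triangles,
                         normals = NULL),
                    class = "surface_mesh")
  mesh$normals <- if (is.null(normals)) vertex_normals(mesh) else {
    normals <- as.matrix(normals)
    if (!all(dim(normals) == dim(vertices))) stop("normals dimension mismatch")
    normals
  }
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d triangles, area %.1f um^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

# raw per-triangle areas from matrices (internal)
triangle_areas_ <- function(V, F) {
  e1 <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  e2 <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  cx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  cy <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  cz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Per-triangle areas
#' @param mesh a [surface_mesh()].
#' @return numeric vector of triangle areas (µm²).
#' @export
triangle_areas <- function(mesh) triangle_areas_(mesh$vertices, mesh$triangles)

#' Total mesh surface area
#' @param mesh a [surface_mesh()].
#' @return total area (µm²).
#' @export
mesh_area <- function(mesh) sum(triangle_areas(mesh))

#' Area of one segmented cell
#'
#' Sum of the areas of the mesh triangles carrying the given label, i.e. the
#' cell's area measured on the curved surface.
#'
#' @param mesh a [surface_mesh()].
#' @param segmentation a [cell_segmentation()] for `mesh`.
#' @param cell_id cell label.
#' @return area (µm²).
#' @export
cell_area <- function(mesh, segmentation, cell_id) {
  lab <- seg_labels(segmentation)
  if (!cell_id %in% lab) stop("unknown cell_id: ", cell_id)
  sum(triangle_areas(mesh)[lab == cell_id])
}

#' Areas of all cells
#' @inheritParams cell_area
#' @return named numeric vector, one entry per positive label.
#' @export
cell_areas <- function(mesh, segmentation) {
  lab <- seg_labels(segmentation)
  keep <- lab > 0L
  a <- rowsum(triangle_areas(mesh)[keep], lab[keep])
  setNames(as.numeric(a), rownames(a))
}

#' Vertex normals (area-weighted, outward)
#' @param mesh a [surface_mesh()] (normals slot ignored).
#' @return n x 3 matrix of unit normals with positive mean z.
#' @export
vertex_normals <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  e1 <- V[F[, 2L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  e2 <- V[F[, 3L], , drop = FALSE] - V[F[, 1L], , drop = FALSE]
  fn <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
              e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
              e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  idx <- as.vector(F)
  acc <- rowsum(rbind(fn, fn, fn), idx)
  n <- matrix(0, nrow(V), 3L)
  n[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n <- n / len
  if (mean(n[, 3L]) < 0) n <- -n
  n
}

#' Triangulate a heightmap into a surface mesh
#'
#' One vertex per (x, y) grid node at height `H[iy, ix]`; two triangles per
#' grid quad, oriented counter-clockwise seen from +z.
#'
#' @param H numeric matrix of heights (µm), rows = y, columns = x.
#' @param dx,dy grid spacing (µm).
#' @return a [surface_mesh()]. Vertex for grid node (iy, ix) has index
#'   `(ix - 1) * nrow(H) + iy`.
#' @export
heightmap_mesh <- function(H, dx, dy) {
  ny <- nrow(H); nx <- ncol(H)
  xs <- rep((seq_len(nx) - 1) * dx, each = ny)
  ys <- rep((seq_len(ny) - 1) * dy, times = nx)
  V <- cbind(x = xs, y = ys, z = as.vector(H))
  iy <- rep(seq_len(ny - 1L), times = nx - 1L)
  ix <- rep(seq_len(nx - 1L), each = ny - 1L)
  a <- (ix - 1L) * ny + iy        # (iy, ix)
  b <- (ix - 1L) * ny + iy + 1L   # (iy+1, ix)
  cc <- ix * ny + iy              # (iy, ix+1)
  d <- ix * ny + iy + 1L          # (iy+1, ix+1)
  F <- rbind(cbind(a, cc, d), cbind(a, d, b))
  surface_mesh(V, F)
}

# CSR edge graph of a mesh, cached on the object if present
mesh_graph <- function(mesh) {
  g <- attr(mesh, "edge_csr")
  if (is.null(g)) g <- cpp_edge_csr(mesh$vertices, mesh$triangles)
  g
}

# assign each vertex the label of the majority of its incident triangles
# (ties -> lowest label); 0 where no labeled triangle touches the vertex
vertex_labels_from_triangles <- function(mesh, tri_labels) {
  F <- mesh$triangles
  nv <- nrow(mesh$vertices)
  v <- as.vector(F)
  lab <- rep(as.integer(tri_labels), 3L)
  keep <- lab > 0L
  v <- v[keep]; lab <- lab[keep]
  if (!length(v)) return(integer(nv))
  o <- order(v, lab)
  v <- v[o]; lab <- lab[o]
  new_run <- c(TRUE, v[-1L] != v[-length(v)] | lab[-1L] != lab[-length(lab)])
  rid <- cumsum(new_run)
  cnt <- tabulate(rid)
  rv <- v[new_run]; rl <- lab[new_run]
  o2 <- order(rv, -cnt, rl)
  first <- !duplicated(rv[o2])
  out <- integer(nv)
  out[rv[o2][first]] <- rl[o2][first]
  out
}
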