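#' Discrete Gaussian curvature at a fixed neighborhood radius
#'
#' Estimates per-vertex Gaussian curvature K (µm^-2) by fitting a quadric
#' height function to all vertices within a geodesic radius of each vertex,
#' in the tangent frame of its normal. The geodesic neighborhood is taken
#' over the mesh edge graph (Dijkstra), which realizes a fixed physical
#' neighborhood — 10 µm by default — independent of mesh resolution. K is
#' the determinant of the shape operator of the fitted quadric at the
#' vertex.
#'
#' Vertices with fewer than `min_neighbors` in-radius neighbors, or a
#' rank-deficient fit, are flagged undefined (`NA`), never silently zeroed.
#'
#' @param mesh a [surface_mesh()].
#' @param radius neighborhood radius (µm). Must exceed twice the median
#'   edge length.
#' @param min_neighbors minimum in-radius neighbors for a defined estimate.
#' @param max_fit_neighbors cap on neighbors entering the fit; larger balls
#'   are subsampled evenly in geodesic-distance order (deterministic).
#' @param smooth_iterations optional post-hoc smoothing passes (averaging K
#'   over the 1-ring); 0 (off) by default.
#' @return object of class `curvature_field`: list with `K` (per-vertex,
#'   `NA` where undefined), `defined` (logical), `n_neighbors`, `radius`.
#' @export
gaussian_curvature <- function(mesh, radius = 10, min_neighbors = 6L,
                               max_fit_neighbors = 250L,
                               smooth_iterations = 0L) {
  g <- mesh_graph(mesh)
  med_edge <- median(g$wt)
  if (radius <= 2 * med_edge)
    stop(sprintf("radius (%.3g) must exceed 2x the median edge length (%.3g)",
                 radius, med_edge))
  res <- cpp_ball_curvature(mesh$vertices, mesh$normals, g$ptr, g$idx, g$wt,
                            radius, as.integer(min_neighbors),
                            as.integer(max_fit_neighbors))
  K <- res$K
  if (smooth_iterations > 0L) {
    for (it in seq_len(smooth_iterations)) {
      Kfill <- ifelse(is.na(K), 0, K)
      wts <- as.numeric(!is.na(K))
      num <- Kfill; den <- wts
      # average over the 1-ring (including self)
      src <- rep.int(seq_along(g$ptr[-length(g$ptr)]),
                     diff(g$ptr))
      num <- num + as.numeric(rowsum(Kfill[g$idx], src, reorder = TRUE))
      den <- den + as.numeric(rowsum(wts[g$idx], src, reorder = TRUE))
      K <- ifelse(den > 0 & !is.na(res$K), num / den, NA_real_)
    }
  }
  structure(list(K = K, defined = !is.na(K), n_neighbors = res$n_neighbors,
                 radius = radius),
            class = "curvature_field")
}

#' @export
print.curvature_field <- function(x, ...) {
  cat(sprintf("curvature_field: %d vertices (%d undefined), radius %g um\n",
              length(x$K), sum(!x$defined), x$radius))
  cat(sprintf("  K range: [%.4g, %.4g] um^-2\n",
              min(x$K, na.rm = TRUE), max(x$K, na.rm = TRUE)))
  invisible(x)
}

#' Angle-defect (Gauss-Bonnet) Gaussian curvature
#'
#' Independent low-level estimator: K at a vertex is its angle defect
#' (2*pi minus the sum of incident triangle angles) divided by the
#' barycentric vertex area. Resolution-dependent, so it is not used for the
#' fixed-radius curvature maps, but it is exact in the Gauss-Bonnet sense
#' and serves as a cross-check of curvature sign.
#'
#' @param mesh a [surface_mesh()].
#' @return numeric vector of per-vertex K (µm^-2); `NA` on boundary
#'   vertices, where the defect is undefined.
#' @export
angle_defect_curvature <- function(mesh) {
  V <- mesh$vertices; F <- mesh$triangles
  nv <- nrow(V)
  ang <- matrix(0, nrow(F), 3L)
  for (c0 in 1:3) {
    i <- F[, c0]; j <- F[, c0 %% 3L + 1L]; k <- F[, (c0 + 1L) %% 3L + 1L]
    e1 <- V[j, , drop = FALSE] - V[i, , drop = FALSE]
    e2 <- V[k, , drop = FALSE] - V[i, , drop = FALSE]
    cosang <- rowSums(e1 * e2) /
      (sqrt(rowSums(e1^2)) * sqrt(rowSums(e2^2)))
    ang[, c0] <- acos(pmin(1, pmax(-1, cosang)))
  }
  defect <- rep(2 * pi, nv)
  acc <- rowsum(as.vector(ang), as.vector(F))
  defect[as.integer(rownames(acc))] <-
    2 * pi - as.numeric(acc)
  ta <- triangle_areas(mesh)
  varea <- rep(0, nv)
  aacc <- rowsum(rep(ta / 3, 3L), as.vector(F))
  varea[as.integer(rownames(aacc))] <- as.numeric(aacc)
  K <- ifelse(varea > 0, defect / varea, NA_real_)
  # boundary vertices: edges used by a single triangle
  ek <- cbind(c(F[, 1L], F[, 2L], F[, 3L]), c(F[, 2L], F[, 3L], F[, 1L]))
  key <- paste(pmin(ek[, 1L], ek[, 2L]), pmax(ek[, 1L], ek[, 2L]))
  single <- names(which(table(key) == 1L))
  if (length(single)) {
    bv <- unique(as.integer(unlist(strsplit(single, " "))))
    K[bv] <- NA_real_
  }
  K
}

#' Export a curvature field
#'
#' Writes the per-vertex field as a PLY vertex property
#' `gaussian_curvature` and/or a CSV (`vertex`, `x`, `y`, `z`, `K`,
#' `defined`).
#'
#' @param mesh a [surface_mesh()].
#' @param field a `curvature_field` from [gaussian_curvature()].
#' @param ply,csv output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_curvature <- function(mesh, field, ply = NULL, csv = NULL) {
  out <- character()
  if (!is.null(ply)) {
    K <- ifelse(is.na(field$K), 0, field$K)
    write_ply(mesh, ply, vertex_props = list(gaussian_curvature = K))
    out <- c(out, ply)
  }
  if (!is.null(csv)) {
    write.csv(data.frame(vertex = seq_along(field$K),
                         x = mesh$vertices[, 1L], y = mesh$vertices[, 2L],
                         z = mesh$vertices[, 3L], K = field$K,
                         defined = field$defined),
              csv, row.names = FALSE)
    out <- c(out, csv)
  }
  invisible(out)
}
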