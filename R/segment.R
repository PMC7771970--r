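#' Per-triangle cell labeling of a mesh
#'
#' Maps each mesh triangle to a positive integer cell label; 0 marks
#' unassigned triangles, which all area computations ignore.
#'
#' @param labels integer vector, one label per triangle.
#' @return object of class `cell_segmentation`.
#' @export
cell_segmentation <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || any(labels < 0L))
    stop("labels must be non-negative integers")
  structure(list(labels = labels), class = "cell_segmentation")
}

#' @export
print.cell_segmentation <- function(x, ...) {
  cat(sprintf("cell_segmentation: %d triangles, %d cells, %d unassigned\n",
              length(x$labels), length(unique(x$labels[x$labels > 0L])),
              sum(x$labels == 0L)))
  invisible(x)
}

#' Triangle labels of a segmentation
#' @param segmentation a [cell_segmentation()].
#' @return integer vector of per-triangle labels.
#' @export
seg_labels <- function(segmentation) segmentation$labels

#' Extract the epidermal surface from a wall-stain stack
#'
#' 2.5D surface extraction: for each (x, y) column the topmost voxel above
#' `threshold` defines a height (quantized at the z step); the height map
#' is 3x3 median-filtered and triangulated on the pixel grid, giving a
#' heightmap [surface_mesh()] in µm.
#'
#' @param stack a [volume_stack()].
#' @param threshold intensity threshold; columns with no voxel above it are
#'   filled from neighbors, but if more than half of all columns are empty
#'   the stack is rejected (not a surface).
#' @param smooth_sigma Gaussian smoothing of the height map (µm) applied
#'   after the median filter; damps the z-step quantization noise that
#'   otherwise dominates curvature estimates on nearly flat apices. Set 0
#'   to disable.
#' @return a [surface_mesh()].
#' @export
extract_surface <- function(stack, threshold, smooth_sigma = 2) {
  arr <- stack$intensities
  d <- dim(arr)
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  if (prod(d) == 0L) stop("empty stack")
  M <- matrix(arr > threshold, nz, ny * nx)
  hasany <- colSums(M) > 0L
  if (mean(hasany) < 0.5)
    stop("no voxel above threshold in more than half of the columns; ",
         "not a surface")
  top <- max.col(t(M), ties.method = "first")
  H <- matrix(stack$z_top - (top - 1L) * stack$voxel_size["z"], ny, nx)
  H[matrix(!hasany, ny, nx)] <- NA_real_
  H <- cpp_median3(H)
  it <- 0L
  while (anyNA(H) && it < 20L) {  # grow into empty columns
    filled <- cpp_median3(H)
    H[is.na(H)] <- filled[is.na(H)]
    it <- it + 1L
  }
  if (anyNA(H)) stop("could not fill empty surface columns")
  if (smooth_sigma > 0)
    H <- gauss_blur(H, smooth_sigma / mean(stack$voxel_size[c("y", "x")]))
  heightmap_mesh(H, dx = stack$voxel_size["x"], dy = stack$voxel_size["y"])
}

# separable Gaussian blur with replicated edges (sigma in pixels)
gauss_blur <- function(M, sigma_px) {
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(X) {
    n <- nrow(X)
    Xp <- X[c(rep(1L, r), seq_len(n), rep(n, r)), , drop = FALSE]
    out <- matrix(0, n, ncol(X))
    for (i in seq_along(k))
      out <- out + k[i] * Xp[i:(i + n - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(M))))
}

#' Project wall-stain signal onto mesh vertices
#'
#' Per vertex, the mean (trilinearly interpolated) stack intensity sampled
#' along the inward normal across a depth band — 0-4 µm by default, the
#' outer cell layer where the anticlinal walls live. Vertices whose ray
#' exits the stack are flagged undefined (`NA`); [segment_cells()] excludes
#' them from the watershed.
#'
#' @param stack a [volume_stack()].
#' @param mesh a [surface_mesh()] in the same µm frame as the stack.
#' @param band depth band (µm), `band[1] < band[2]`.
#' @return numeric per-vertex intensity with attribute `defined` (logical).
#' @export
project_wall_signal <- function(stack, mesh, band = c(0, 4)) {
  if (band[1L] >= band[2L]) stop("band must satisfy band_min < band_max")
  vs <- stack$voxel_size
  vals <- cpp_band_sample(stack$intensities, dim(stack$intensities),
                          vs["z"], vs["y"], vs["x"], stack$z_top,
                          mesh$vertices, -mesh$normals,
                          band[1L], band[2L], min(vs) / 2)
  structure(as.numeric(vals), defined = !is.na(vals))
}

#' Seeded watershed cell segmentation on the mesh vertex graph
#'
#' Floods the wall-signal field over the vertex graph of the mesh from
#' marker seeds (priority flood), so that basin boundaries follow wall
#' ridges on the curved surface and cell areas are measured on the surface,
#' not in the image plane. Without seeds, markers are the regional minima
#' of the field after h-minima suppression with `h` equal to
#' `h_fraction` of the dynamic range. Basins smaller than `min_cell_area`
#' are merged into the neighbor with the longest shared boundary.
#'
#' @param mesh a [surface_mesh()].
#' @param wall_signal per-vertex intensity from [project_wall_signal()]
#'   (must be defined on at least 90% of vertices).
#' @param seeds optional k x 3 matrix of seed points (snapped to nearest
#'   vertices; labels 1..k in row order).
#' @param min_cell_area merge threshold (µm²); well below any epidermal
#'   cell, it removes watershed slivers only.
#' @param h_fraction h-minima depth as a fraction of the field's dynamic
#'   range (unseeded mode).
#' @return a [cell_segmentation()] with attribute `vertex_labels`.
#' @export
segment_cells <- function(mesh, wall_signal, seeds = NULL, min_cell_area = 4,
                          h_fraction = 0.1) {
  field <- as.numeric(wall_signal)
  defined <- attr(wall_signal, "defined")
  if (is.null(defined)) defined <- !is.na(field)
  if (mean(defined) < 0.9)
    stop("wall signal undefined on more than 10% of vertices")
  rng <- range(field[defined])
  field[!defined] <- rng[2L] + 0.1 * diff(rng)  # flooded last
  g <- mesh_graph(mesh)
  nv <- nrow(mesh$vertices)
  seedlab <- integer(nv)
  if (is.null(seeds)) {
    seedlab <- cpp_hminima_seeds(g$ptr, g$idx, field,
                                 h_fraction * diff(rng))
  } else {
    seeds <- matrix(as.numeric(seeds), ncol = 3L)
    for (i in seq_len(nrow(seeds))) {
      v <- snap_vertex(mesh, seeds[i, ])
      if (seedlab[v] != 0L) {  # collision: take the nearest free vertex
        frontier <- v
        seen <- v
        while (seedlab[v] != 0L && length(frontier)) {
          nxt <- setdiff(unlist(lapply(frontier, function(u)
            g$idx[g$ptr[u]:(g$ptr[u + 1L] - 1L)])), seen)
          free <- nxt[seedlab[nxt] == 0L]
          if (length(free)) { v <- free[1L]; break }
          seen <- c(seen, nxt)
          frontier <- nxt
        }
      }
      seedlab[v] <- i
    }
  }
  if (!any(seedlab > 0L)) stop("zero watershed seeds found")
  vlab <- cpp_watershed(g$ptr, g$idx, field, seedlab)
  F <- mesh$triangles
  l1 <- vlab[F[, 1L]]; l2 <- vlab[F[, 2L]]; l3 <- vlab[F[, 3L]]
  tri_lab <- ifelse(l1 == l2 | l1 == l3, l1,
                    ifelse(l2 == l3, l2, pmin(l1, l2, l3)))
  tri_lab <- merge_small_cells(mesh, tri_lab, min_cell_area)
  out <- cell_segmentation(tri_lab)
  attr(out, "vertex_labels") <- vlab
  out
}

# merge labels below min_area into the neighbor with the longest shared
# boundary, smallest first
merge_small_cells <- function(mesh, tri_lab, min_area) {
  if (min_area <= 0) return(tri_lab)
  ta <- triangle_areas(mesh)
  repeat {
    ar <- rowsum(ta, tri_lab)
    labs <- as.integer(rownames(ar))
    small <- labs[ar[, 1L] < min_area & labs > 0L]
    if (!length(small) || length(labs) <= 1L) break
    victim <- small[which.min(ar[match(small, labs), 1L])]
    sh <- shared_boundaries(mesh, tri_lab, victim)
    if (!nrow(sh)) {  # isolated label: drop to unassigned
      tri_lab[tri_lab == victim] <- 0L
      next
    }
    tri_lab[tri_lab == victim] <- sh$neighbor[which.max(sh$length)]
  }
  tri_lab
}

# boundary lengths between one label and each of its neighbors
shared_boundaries <- function(mesh, tri_lab, label) {
  F <- mesh$triangles
  V <- mesh$vertices
  ek <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(1L, 3L)])
  own <- rep(tri_lab, 3L)
  lo <- pmin(ek[, 1L], ek[, 2L]); hi <- pmax(ek[, 1L], ek[, 2L])
  key <- (lo - 1) * nrow(V) + hi
  o <- order(key)
  key <- key[o]; own <- own[o]; lo <- lo[o]; hi <- hi[o]
  dup <- which(key[-1L] == key[-length(key)])
  a <- own[dup]; b <- own[dup + 1L]
  sel <- (a == label) != (b == label)
  if (!any(sel)) return(data.frame(neighbor = integer(), length = numeric()))
  nb <- ifelse(a[sel] == label, b[sel], a[sel])
  len <- sqrt(rowSums((V[lo[dup][sel], , drop = FALSE] -
                         V[hi[dup][sel], , drop = FALSE])^2))
  agg <- rowsum(len, nb)
  data.frame(neighbor = as.integer(rownames(agg)), length = agg[, 1L])
}

#' Cell adjacency graph of a segmentation
#'
#' Two cells are adjacent iff they share at least one mesh edge. The graph
#' is the substrate of topological zonation: central/peripheral zones are
#' defined by cell-graph distance from the summit cell.
#'
#' @param segmentation a [cell_segmentation()].
#' @param mesh the segmented [surface_mesh()].
#' @return object of class `cell_graph`: list with `nodes` (labels) and
#'   `adjacency` (named list of neighbor label vectors); symmetric, no
#'   self-loops.
#' @export
build_cell_graph <- function(segmentation, mesh) {
  tri_lab <- seg_labels(segmentation)
  F <- mesh$triangles
  nv <- nrow(mesh$vertices)
  ek <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(1L, 3L)])
  own <- rep(tri_lab, 3L)
  lo <- pmin(ek[, 1L], ek[, 2L]); hi <- pmax(ek[, 1L], ek[, 2L])
  key <- (lo - 1) * nv + hi
  o <- order(key)
  key <- key[o]; own <- own[o]
  dup <- which(key[-1L] == key[-length(key)])
  a <- own[dup]; b <- own[dup + 1L]
  sel <- a != b & a > 0L & b > 0L
  pairs <- unique(cbind(pmin(a[sel], b[sel]), pmax(a[sel], b[sel])))
  nodes <- sort(unique(tri_lab[tri_lab > 0L]))
  adj <- setNames(vector("list", length(nodes)), as.character(nodes))
  for (nd in nodes) adj[[as.character(nd)]] <- integer()
  if (nrow(pairs)) {
    sp1 <- split(pairs[, 2L], pairs[, 1L])
    sp2 <- split(pairs[, 1L], pairs[, 2L])
    for (nm in names(sp1))
      adj[[nm]] <- sort(unique(c(adj[[nm]], sp1[[nm]])))
    for (nm in names(sp2))
      adj[[nm]] <- sort(unique(c(adj[[nm]], sp2[[nm]])))
  }
  structure(list(nodes = nodes, adjacency = adj), class = "cell_graph")
}

#' @export
print.cell_graph <- function(x, ...) {
  cat(sprintf("cell_graph: %d cells, %d adjacencies\n", length(x$nodes),
              sum(lengths(x$adjacency)) / 2))
  invisible(x)
}

#' Breadth-first ring distances on a cell graph
#'
#' @param graph a [build_cell_graph()] graph.
#' @param start starting cell label.
#' @param restrict optional set of labels the search may visit.
#' @return named integer vector of graph distances (names = cell labels);
#'   unreachable cells are absent.
#' @export
bfs_rings <- function(graph, start, restrict = NULL) {
  allowed <- if (is.null(restrict)) graph$nodes else intersect(graph$nodes, restrict)
  if (!start %in% allowed) stop("start cell not in graph (or not in restrict)")
  dist <- setNames(rep(NA_integer_, length(allowed)), as.character(allowed))
  dist[as.character(start)] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(graph$adjacency[as.character(frontier)],
                         use.names = FALSE))
    nxt <- nxt[nxt %in% allowed]
    nxt <- nxt[is.na(dist[as.character(nxt)])]
    dist[as.character(nxt)] <- d
    frontier <- nxt
  }
  dist[!is.na(dist)]
}
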