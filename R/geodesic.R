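#' On-surface curvilinear distance between two points
#'
#' Arc length of a shortest on-surface polyline between two points,
#' optionally constrained through a third (`via`), e.g. the meristem summit
#' when measuring the distance between primordia on opposite sides of the
#' apex. Computed by Dijkstra over a Steiner-augmented edge graph — mesh
#' vertices plus two points per edge plus face centroids, completely
#' connected within each face — with the query points linked exactly into
#' the triangle fan nearest to them. The augmentation supplies the in-face
#' directions a bare edge graph lacks, keeping the metric distortion a few
#' tenths of a percent.
#'
#' @param mesh a [surface_mesh()].
#' @param a,b 3D points (length-3 numeric) on or near the surface.
#' @param via optional intermediate 3D point.
#' @return distance in µm, with attribute `path` (the polyline, k x 3).
#'   Always at least the Euclidean distance |a - b| when `via` is `NULL`.
#' @export
curvilinear_distance <- function(mesh, a, b, via = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3L || length(b) != 3L) stop("points must be length-3 xyz")
  if (!is.null(via)) {
    d1 <- curvilinear_distance(mesh, a, via)
    d2 <- curvilinear_distance(mesh, via, b)
    return(structure(as.numeric(d1) + as.numeric(d2),
                     path = rbind(attr(d1, "path"),
                                  attr(d2, "path")[-1L, , drop = FALSE])))
  }
  if (all(a == b))
    return(structure(0, path = matrix(a, 1L, 3L)))
  # canonical endpoint order makes the result exactly symmetric in (a, b)
  swapped <- FALSE
  cmp <- sign(a - b)
  first <- cmp[cmp != 0][1L]
  if (!is.na(first) && first > 0) {
    tmp <- a; a <- b; b <- tmp
    swapped <- TRUE
  }
  ag <- augmented_graph(mesh)
  n0 <- nrow(ag$coords)
  ca <- endpoint_links(mesh, ag, a)
  cb <- endpoint_links(mesh, ag, b)
  lo <- c(ag$lo, rep(n0 + 1L, length(ca$nodes)), rep(n0 + 2L, length(cb$nodes)))
  hi <- c(ag$hi, ca$nodes, cb$nodes)
  wt <- c(ag$wt, ca$w, cb$w)
  coords <- rbind(ag$coords, matrix(a, 1L), matrix(b, 1L))
  aa <- c(lo, hi); bb <- c(hi, lo); ww <- c(wt, wt)
  o <- order(aa)
  aa <- aa[o]; bb <- bb[o]; ww <- ww[o]
  deg <- tabulate(aa, nbins = n0 + 2L)
  ptr <- as.integer(c(1L, 1L + cumsum(deg)))
  r <- cpp_dijkstra_path(ptr, as.integer(bb), ww, n0 + 1L, n0 + 2L)
  if (!length(r$path)) stop("points lie on disconnected mesh components")
  tp <- tighten_path(mesh, ag, r$path, coords)
  path <- if (swapped) tp$path[rev(seq_len(nrow(tp$path))), , drop = FALSE]
          else tp$path
  structure(tp$length, path = path)
}

# slide interior path nodes along their supporting mesh feature (edge
# segment or face) to shorten the polyline; the result stays on the
# surface, so the length can only move toward the true geodesic from above
tighten_path <- function(mesh, ag, node_ids, coords, sweeps = 8L) {
  P <- coords[node_ids, , drop = FALSE]
  k <- nrow(P)
  if (k <= 2L) return(list(path = P, length = path_length(P)))
  nv <- nrow(mesh$vertices)
  ne <- (nrow(ag$coords) - nv - nrow(mesh$triangles)) / 2L
  # support of each interior node: endpoints of its edge, or face corners
  supports <- lapply(node_ids, function(id) {
    if (id <= nv) NULL
    else if (id <= nv + 2L * ne) {
      e <- ag$edge_ends[((id - nv - 1L) %% ne) + 1L, ]
      rbind(mesh$vertices[e[1L], ], mesh$vertices[e[2L], ])
    } else if (id <= nv + 2L * ne + nrow(mesh$triangles)) {
      f <- id - nv - 2L * ne
      mesh$vertices[mesh$triangles[f, ], , drop = FALSE]
    } else NULL
  })
  seg_min <- function(A, B, p, q) {  # golden-section along segment A-B
    f <- function(t) {
      x <- A + t * (B - A)
      sqrt(sum((x - p)^2)) + sqrt(sum((x - q)^2))
    }
    gr <- (sqrt(5) - 1) / 2
    lo <- 0; hi <- 1
    c1 <- hi - gr * (hi - lo); c2 <- lo + gr * (hi - lo)
    f1 <- f(c1); f2 <- f(c2)
    for (it in 1:30) {
      if (f1 < f2) { hi <- c2; c2 <- c1; f2 <- f1
        c1 <- hi - gr * (hi - lo); f1 <- f(c1)
      } else { lo <- c1; c1 <- c2; f1 <- f2
        c2 <- lo + gr * (hi - lo); f2 <- f(c2) }
    }
    t0 <- (lo + hi) / 2
    list(x = A + t0 * (B - A), v = f(t0))
  }
  for (sw in seq_len(sweeps)) {
    for (i in 2:(k - 1L)) {
      sup <- supports[[i]]
      if (is.null(sup)) next
      p <- P[i - 1L, ]; q <- P[i + 1L, ]
      if (nrow(sup) == 2L) {
        P[i, ] <- seg_min(sup[1L, ], sup[2L, ], p, q)$x
      } else {
        best <- list(x = P[i, ], v = sqrt(sum((P[i, ] - p)^2)) +
                       sqrt(sum((P[i, ] - q)^2)))
        for (ed in list(c(1L, 2L), c(2L, 3L), c(1L, 3L))) {
          cand <- seg_min(sup[ed[1L], ], sup[ed[2L], ], p, q)
          if (cand$v < best$v) best <- cand
        }
        P[i, ] <- best$x
      }
    }
  }
  list(path = P, length = path_length(P))
}

path_length <- function(P) {
  if (nrow(P) < 2L) return(0)
  sum(sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

snap_vertex <- function(mesh, p) {
  p <- as.numeric(p)
  if (length(p) != 3L) stop("points must be length-3 xyz")
  V <- mesh$vertices
  which.min((V[, 1L] - p[1L])^2 + (V[, 2L] - p[2L])^2 + (V[, 3L] - p[3L])^2)
}

# connect a query point to every augmented node of the triangle fan around
# its nearest vertex
endpoint_links <- function(mesh, ag, p) {
  iv <- snap_vertex(mesh, p)
  F <- mesh$triangles
  faces <- which(F[, 1L] == iv | F[, 2L] == iv | F[, 3L] == iv)
  nodes <- unique(as.vector(ag$face_nodes[faces, , drop = FALSE]))
  w <- sqrt((ag$coords[nodes, 1L] - p[1L])^2 +
              (ag$coords[nodes, 2L] - p[2L])^2 +
              (ag$coords[nodes, 3L] - p[3L])^2)
  list(nodes = nodes, w = w)
}

# Steiner-augmented graph: vertices + two points per edge (at 1/3 and 2/3)
# + face centroids, completely connected within each face.
augmented_graph <- function(mesh) {
  cached <- attr(mesh, "augmented_graph")
  if (!is.null(cached)) return(cached)
  V <- mesh$vertices; F <- mesh$triangles
  nv <- nrow(V); nf <- nrow(F)
  ek <- rbind(F[, c(1L, 2L)], F[, c(2L, 3L)], F[, c(1L, 3L)])
  elo <- pmin(ek[, 1L], ek[, 2L]); ehi <- pmax(ek[, 1L], ek[, 2L])
  ekey <- (elo - 1) * nv + ehi
  ue <- !duplicated(ekey)
  edges <- cbind(elo[ue], ehi[ue])
  ne <- nrow(edges)
  eid <- match(ekey, ekey[ue])              # per face-corner edge -> unique id
  mid_of <- matrix(eid, nf, 3L)             # columns: (1,2), (2,3), (1,3)
  P1 <- V[edges[, 1L], , drop = FALSE] +
    (V[edges[, 2L], , drop = FALSE] - V[edges[, 1L], , drop = FALSE]) / 3
  P2 <- V[edges[, 1L], , drop = FALSE] +
    2 * (V[edges[, 2L], , drop = FALSE] - V[edges[, 1L], , drop = FALSE]) / 3
  C <- (V[F[, 1L], , drop = FALSE] + V[F[, 2L], , drop = FALSE] +
          V[F[, 3L], , drop = FALSE]) / 3
  coords <- rbind(V, P1, P2, C)
  # per-face node set: 3 vertices, 6 edge points, 1 centroid
  nodes_f <- cbind(F[, 1L], F[, 2L], F[, 3L],
                   nv + mid_of[, 1L], nv + ne + mid_of[, 1L],
                   nv + mid_of[, 2L], nv + ne + mid_of[, 2L],
                   nv + mid_of[, 3L], nv + ne + mid_of[, 3L],
                   nv + 2L * ne + seq_len(nf))
  cmb <- utils::combn(10L, 2L)
  E <- cbind(as.vector(nodes_f[, cmb[1L, ]]), as.vector(nodes_f[, cmb[2L, ]]))
  lo <- pmin(E[, 1L], E[, 2L]); hi <- pmax(E[, 1L], E[, 2L])
  keep <- !duplicated((lo - 1) * nrow(coords) + hi)
  lo <- lo[keep]; hi <- hi[keep]
  wt <- sqrt(rowSums((coords[lo, , drop = FALSE] -
                        coords[hi, , drop = FALSE])^2))
  list(lo = lo, hi = hi, wt = wt, coords = coords, face_nodes = nodes_f,
       edge_ends = edges)
}
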