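# Geometric fixtures and independent oracles shared across the suite.

# icosphere of radius r, `sub` midpoint subdivisions
icosphere <- function(r = 1, sub = 3) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  F <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(sub)) {
    mid <- new.env(parent = emptyenv())
    nV <- V
    nF <- matrix(0L, 4L * nrow(F), 3L)
    getm <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mid[[k]])) return(mid[[k]])
      nV <<- rbind(nV, (V[a, ] + V[b, ]) / 2)
      mid[[k]] <- nrow(nV)
      nrow(nV)
    }
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; c <- F[f, 3]
      ab <- getm(a, b); bc <- getm(b, c); ca <- getm(c, a)
      nF[4L * f - 3L, ] <- c(a, ab, ca)
      nF[4L * f - 2L, ] <- c(b, bc, ab)
      nF[4L * f - 1L, ] <- c(c, ca, bc)
      nF[4L * f, ] <- c(ab, bc, ca)
    }
    V <- nV; F <- nF
  }
  V <- V / sqrt(rowSums(V^2)) * r
  surface_mesh(V, F)
}

# cached sphere meshes (expensive to build)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}
sphere25 <- function() cached("sphere25", function() icosphere(25, 4))
sphere30 <- function() cached("sphere30", function() icosphere(30, 4))

# planar grid mesh (z = 0) with given extent/spacing
plane_mesh <- function(extent = 40, d = 1)
  heightmap_mesh(matrix(0, extent / d + 1, extent / d + 1), d, d)

# saddle z = (x^2 - y^2) / (2 c), centered grid
saddle_mesh <- function(c0 = 20, extent = 20, d = 1) {
  xs <- seq(-extent, extent, by = d)
  H <- outer(xs, xs, function(y, x) (x^2 - y^2) / (2 * c0))
  heightmap_mesh(H, d, d)
}

# smooth random-bump heightmap (sum of Gaussians), fixed by seed
bump_mesh <- function(seed = 7, extent = 40, d = 1, scale = 1) {
  set.seed(seed)
  xs <- seq(0, extent, by = d)
  H <- matrix(0, length(xs), length(xs))
  for (k in 1:5) {
    cx <- runif(1, 8, extent - 8); cy <- runif(1, 8, extent - 8)
    s <- runif(1, 4, 8); a <- runif(1, -4, 6)
    H <- H + a * outer(exp(-(xs - cy)^2 / (2 * s^2)),
                       exp(-(xs - cx)^2 / (2 * s^2)))
  }
  m <- heightmap_mesh(H * scale, d * scale, d * scale)
  m
}

# hexagonal tessellation fixture: planar mesh labeled by nearest hex-lattice
# center; the cell graph of the interior is the honeycomb adjacency
hex_fixture <- function(rings = 6, spacing = 2, d = 0.25) {
  centers <- matrix(c(0, 0), 1L)
  for (q in -rings:rings) for (r in -rings:rings) {
    if (abs(q + r) > rings || (q == 0 && r == 0)) next
    centers <- rbind(centers,
                     c(spacing * (q + r / 2), spacing * sqrt(3) / 2 * r))
  }
  ext <- spacing * (rings + 1.2)
  n <- round(2 * ext / d) + 1
  H <- matrix(0, n, n)
  mesh <- heightmap_mesh(H, d, d)
  V <- mesh$vertices
  ctr <- cbind(centers[, 1] + ext, centers[, 2] + ext, 0)
  tc <- (V[mesh$triangles[, 1], ] + V[mesh$triangles[, 2], ] +
           V[mesh$triangles[, 3], ]) / 3
  tc[, 3] <- 0
  lab <- integer(nrow(tc))
  for (i in seq_len(nrow(ctr))) {
    dd <- (tc[, 1] - ctr[i, 1])^2 + (tc[, 2] - ctr[i, 2])^2
    if (i == 1) { best <- dd; lab[] <- 1L }
    else { sel <- dd < best; lab[sel] <- i; best[sel] <- dd[sel] }
  }
  list(mesh = mesh, segmentation = cell_segmentation(lab), central = 1L,
       n_centers = nrow(ctr))
}

# brute-force BFS distances over a cell_graph (independent of bfs_rings)
oracle_bfs <- function(graph, start, restrict = NULL) {
  nodes <- if (is.null(restrict)) graph$nodes else intersect(graph$nodes, restrict)
  dist <- setNames(rep(Inf, length(nodes)), as.character(nodes))
  dist[as.character(start)] <- 0
  repeat {
    changed <- FALSE
    for (v in nodes) {
      nbs <- intersect(graph$adjacency[[as.character(v)]], nodes)
      if (!length(nbs)) next
      best <- min(dist[as.character(nbs)]) + 1
      if (best < dist[as.character(v)]) {
        dist[as.character(v)] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- dist[is.finite(dist)]
  storage.mode(out) <- "integer"
  out
}

# O(n^2) shared-edge scan building cell adjacency from scratch (restricted
# to labeled triangles; edges to unlabeled area carry no adjacency)
oracle_cell_adjacency <- function(mesh, segmentation) {
  lab <- seg_labels(segmentation)
  F <- mesh$triangles[lab > 0L, , drop = FALSE]
  lab <- lab[lab > 0L]
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- c(edge_key(F[, 1], F[, 2]), edge_key(F[, 2], F[, 3]),
            edge_key(F[, 1], F[, 3]))
  owner <- rep(lab, 3)
  pairs <- list()
  for (k in unique(keys[duplicated(keys)])) {
    own <- unique(owner[keys == k])
    if (length(own) == 2L)
      pairs[[length(pairs) + 1L]] <- sort(own)
  }
  unique(do.call(rbind, pairs))
}

# area-overlap IoU of each truth cell with its best-matching detected cell
match_iou <- function(mesh, truth, detected) {
  ta <- triangle_areas(mesh)
  lt <- seg_labels(truth); ld <- seg_labels(detected)
  ids <- sort(unique(lt[lt > 0]))
  vapply(ids, function(i) {
    sel <- lt == i
    ov <- rowsum(ta[sel], ld[sel])
    ov <- ov[rownames(ov) != "0", , drop = FALSE]
    if (!nrow(ov)) return(0)
    j <- rownames(ov)[which.max(ov)]
    inter <- ov[j, 1]
    union <- sum(ta[sel]) + sum(ta[ld == as.integer(j)]) - inter
    inter / union
  }, numeric(1))
}

# area-weighted Jaccard of two triangle masks
area_jaccard <- function(mesh, mask_a, mask_b) {
  ta <- triangle_areas(mesh)
  sum(ta[mask_a & mask_b]) / sum(ta[mask_a | mask_b])
}
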