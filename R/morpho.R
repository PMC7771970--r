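#' Summit (central) cell of the apex
#'
#' The cell containing the vertex with the maximal coordinate along the
#' apex axis (+z by default); ties go to the lowest vertex index, and a
#' vertex shared by several cells belongs to the cell owning most of its
#' incident triangles (ties to the lowest label). Deterministic.
#'
#' @param mesh a [surface_mesh()].
#' @param segmentation a [cell_segmentation()].
#' @param axis unit 3-vector; the apex axis.
#' @return the central cell label.
#' @export
find_central_cell <- function(mesh, segmentation, axis = c(0, 0, 1)) {
  tri_lab <- seg_labels(segmentation)
  if (!any(tri_lab > 0L)) stop("empty segmentation")
  proj <- as.numeric(mesh$vertices %*% (axis / sqrt(sum(axis^2))))
  # restrict to vertices of labeled triangles
  labv <- unique(as.vector(mesh$triangles[tri_lab > 0L, ]))
  v <- labv[which.max(proj[labv])]
  cand <- labv[proj[labv] == proj[v]]
  v <- min(cand)                     # tie-break: lowest vertex index
  inc <- which(mesh$triangles[, 1L] == v | mesh$triangles[, 2L] == v |
                 mesh$triangles[, 3L] == v)
  labs <- tri_lab[inc]
  labs <- labs[labs > 0L]
  tl <- table(labs)
  as.integer(names(tl)[order(-tl, as.integer(names(tl)))][1L])
}

# area-weighted mean vertex curvature per cell; vertices weighted by their
# barycentric area, restricted to defined K
cell_mean_curvature <- function(mesh, segmentation, curvature) {
  vlab <- vertex_labels_from_triangles(mesh, seg_labels(segmentation))
  ta <- triangle_areas(mesh)
  varea <- rep(0, nrow(mesh$vertices))
  acc <- rowsum(rep(ta / 3, 3L), as.vector(mesh$triangles))
  varea[as.integer(rownames(acc))] <- as.numeric(acc)
  ok <- curvature$defined & vlab > 0L
  num <- rowsum((varea * curvature$K)[ok], vlab[ok])
  den <- rowsum(varea[ok], vlab[ok])
  setNames(as.numeric(num / den), rownames(num))
}

#' Delimit the meristem region by negative Gaussian curvature
#'
#' The meristem is the connected cell set around the summit bounded by
#' saddle (negative Gaussian curvature) cells: per-cell curvature is the
#' area-weighted mean of defined vertex K within the cell, and the region
#' is grown from the central cell across the cell graph through cells with
#' non-negative K. The first K < 0 cells encountered are the boundary and
#' are excluded from the region by default (`include_boundary` toggles the
#' convention).
#'
#' @param mesh a [surface_mesh()].
#' @param segmentation a [cell_segmentation()].
#' @param curvature a [gaussian_curvature()] field on `mesh` (defined on at
#'   least 90% of the vertices of region-adjacent cells).
#' @param graph the [build_cell_graph()] adjacency.
#' @param central central cell label (see [find_central_cell()]).
#' @param include_boundary count boundary (saddle) cells as part of the
#'   region.
#' @return object of class `meristem_region`: list with `cell_ids`,
#'   `central_cell`, `boundary_cells`, `area` (µm²), `cell_count`,
#'   `cell_K` (per-cell mean curvature).
#' @export
delimit_meristem <- function(mesh, segmentation, curvature, graph, central,
                             include_boundary = FALSE) {
  cellK <- cell_mean_curvature(mesh, segmentation, curvature)
  kof <- function(id) {
    k <- cellK[as.character(id)]
    ifelse(is.na(k), -Inf, k)
  }
  if (is.na(cellK[as.character(central)]) || kof(central) < 0)
    stop("central cell has negative Gaussian curvature; no meristem found")
  visited <- character()
  boundary <- character()
  frontier <- as.character(central)
  seen <- frontier
  while (length(frontier)) {
    visited <- c(visited, frontier)
    nxt <- unique(unlist(graph$adjacency[frontier], use.names = FALSE))
    nxt <- as.character(nxt)
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    kv <- vapply(nxt, kof, numeric(1L))
    boundary <- c(boundary, nxt[kv < 0])
    frontier <- nxt[kv >= 0]
  }
  region_ids <- as.integer(visited)
  boundary_ids <- as.integer(boundary)
  if (include_boundary) region_ids <- c(region_ids, boundary_ids)
  ca <- cell_areas(mesh, segmentation)
  structure(list(cell_ids = sort(region_ids), central_cell = central,
                 boundary_cells = sort(boundary_ids),
                 area = sum(ca[as.character(region_ids)]),
                 cell_count = length(region_ids), cell_K = cellK),
            class = "meristem_region")
}

#' @export
print.meristem_region <- function(x, ...) {
  cat(sprintf(paste0("meristem_region: %d cells, %.0f um^2, central cell %d,",
                     " %d boundary cells\n"),
              x$cell_count, x$area, x$central_cell, length(x$boundary_cells)))
  invisible(x)
}

#' Topological zonation by cell-graph distance
#'
#' Rings are breadth-first cell distances from the central cell restricted
#' to the meristem region; the central zone (CZ) is rings 0-2 and the
#' peripheral ring (PZ_ring) rings 3-5, the cell-distance definition used
#' for central-versus-peripheral cell size comparisons.
#'
#' @param graph a [build_cell_graph()] graph.
#' @param region a [delimit_meristem()] region.
#' @param cz_max last ring of the central zone.
#' @param pz_max last ring of the peripheral ring zone.
#' @return object of class `zone_assignment`: data.frame with `cell_id`,
#'   `ring`, `zone` (`CZ`, `PZ_ring`, `outside`).
#' @export
assign_zones <- function(graph, region, cz_max = 2L, pz_max = 5L) {
  rings <- bfs_rings(graph, region$central_cell, restrict = region$cell_ids)
  ids <- as.integer(names(rings))
  zone <- ifelse(rings <= cz_max, "CZ",
                 ifelse(rings <= pz_max, "PZ_ring", "outside"))
  structure(data.frame(cell_id = ids, ring = as.integer(rings), zone = zone,
                       row.names = NULL),
            class = c("zone_assignment", "data.frame"))
}

#' Morphometric record of one apex
#'
#' Meristem area, cell number, the full per-cell area list and per-zone
#' area summaries (median and mean) for one delimited apex.
#'
#' @param mesh a [surface_mesh()].
#' @param segmentation a [cell_segmentation()].
#' @param region a [delimit_meristem()] region.
#' @param zones an [assign_zones()] assignment.
#' @param apex_id,genotype,condition labels carried into group statistics.
#' @return object of class `morphometric_record`: list with `apex_id`,
#'   `genotype`, `condition`, `meristem_area`, `cell_number`, `cell_areas`
#'   (named, µm²), `median_cell_area`, `mean_cell_area`, `zone_summary`
#'   (data.frame: zone, n, median, mean).
#' @export
summarize_apex <- function(mesh, segmentation, region, zones,
                           apex_id = "apex", genotype = "WT",
                           condition = "NA") {
  ca <- cell_areas(mesh, segmentation)
  areas <- ca[as.character(region$cell_ids)]
  zz <- zones[match(region$cell_ids, zones$cell_id), "zone"]
  zs <- do.call(rbind, lapply(split(as.numeric(areas), zz), function(a)
    data.frame(n = length(a), median = median(a), mean = mean(a))))
  zs <- data.frame(zone = rownames(zs), zs, row.names = NULL)
  structure(list(apex_id = apex_id, genotype = genotype,
                 condition = condition, meristem_area = region$area,
                 cell_number = region$cell_count,
                 cell_areas = setNames(as.numeric(areas),
                                       names(areas)),
                 median_cell_area = median(as.numeric(areas)),
                 mean_cell_area = mean(as.numeric(areas)),
                 zone_summary = zs),
            class = "morphometric_record")
}

#' @export
print.morphometric_record <- function(x, ...) {
  cat(sprintf(paste0("morphometric_record %s (%s, %s): area %.0f um^2, ",
                     "%d cells, median cell area %.2f um^2\n"),
              x$apex_id, x$genotype, x$condition, x$meristem_area,
              x$cell_number, x$median_cell_area))
  invisible(x)
}

#' @export
as.data.frame.morphometric_record <- function(x, ...) {
  data.frame(apex_id = x$apex_id, genotype = x$genotype,
             condition = x$condition, meristem_area = x$meristem_area,
             cell_number = x$cell_number,
             median_cell_area = x$median_cell_area,
             mean_cell_area = x$mean_cell_area)
}

#' Locate developing primordia outside the meristem region
#'
#' Connected components of positive-curvature cells outside the region,
#' each above a minimal area, are the existing primordia P_n. Age rank 1 is
#' the youngest (smallest) bump; azimuths are measured about the apex axis
#' through the region centroid.
#'
#' @param mesh a [surface_mesh()].
#' @param segmentation a [cell_segmentation()].
#' @param curvature a [gaussian_curvature()] field.
#' @param region a [delimit_meristem()] region.
#' @param min_area smallest accepted bump area (µm²).
#' @param min_mean_K smallest accepted area-weighted mean curvature of a
#'   component (µm^-2); genuine primordium bumps sit orders of magnitude
#'   above this floor (K of order 1/radius²), while near-flat flank patches
#'   whose K barely crosses zero are rejected.
#' @return data.frame with `id` (P1 = youngest), `age_rank`, `x`, `y`, `z`
#'   (area-weighted centroid), `azimuth` (degrees in [0, 360)), `area`,
#'   `n_cells`.
#' @export
locate_primordia <- function(mesh, segmentation, curvature, region,
                             min_area = 25, min_mean_K = 1e-4) {
  graph <- build_cell_graph(segmentation, mesh)
  cellK <- region$cell_K
  outside <- setdiff(graph$nodes, c(region$cell_ids, region$boundary_cells))
  pos <- outside[!is.na(cellK[as.character(outside)]) &
                   cellK[as.character(outside)] > 0]
  ca <- cell_areas(mesh, segmentation)
  cents <- cell_centroids(mesh, segmentation)
  orig <- apply(cents[as.character(region$cell_ids), , drop = FALSE] *
                  ca[as.character(region$cell_ids)], 2L, sum) /
    sum(ca[as.character(region$cell_ids)])
  comps <- connected_components(graph, pos)
  out <- lapply(comps, function(cc) {
    area <- sum(ca[as.character(cc)])
    if (area < min_area) return(NULL)
    w <- ca[as.character(cc)]
    meanK <- sum(cellK[as.character(cc)] * w) / sum(w)
    if (meanK < min_mean_K) return(NULL)
    ctr <- apply(cents[as.character(cc), , drop = FALSE] * w, 2L, sum) / sum(w)
    data.frame(x = ctr[1L], y = ctr[2L], z = ctr[3L],
               azimuth = (atan2(ctr[2L] - orig[2L],
                                ctr[1L] - orig[1L]) * 180 / pi) %% 360,
               area = area, n_cells = length(cc))
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(out))
    return(data.frame(id = character(), age_rank = integer(), x = numeric(),
                      y = numeric(), z = numeric(), azimuth = numeric(),
                      area = numeric(), n_cells = integer()))
  out <- out[order(out$area), , drop = FALSE]
  out <- data.frame(id = paste0("P", seq_len(nrow(out))),
                    age_rank = seq_len(nrow(out)), out, row.names = NULL)
  out
}

# area-weighted triangle centroids aggregated per cell
cell_centroids <- function(mesh, segmentation) {
  tri_lab <- seg_labels(segmentation)
  keep <- tri_lab > 0L
  tc <- (mesh$vertices[mesh$triangles[, 1L], , drop = FALSE] +
           mesh$vertices[mesh$triangles[, 2L], , drop = FALSE] +
           mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]) / 3
  ta <- triangle_areas(mesh)
  num <- rowsum(tc[keep, , drop = FALSE] * ta[keep], tri_lab[keep])
  den <- rowsum(ta[keep], tri_lab[keep])
  out <- num / as.numeric(den)
  rownames(out) <- rownames(num)
  out
}

# connected components of a node subset on the cell graph
connected_components <- function(graph, nodes) {
  nodes <- as.integer(nodes)
  left <- nodes
  comps <- list()
  while (length(left)) {
    frontier <- left[1L]
    comp <- frontier
    left <- setdiff(left, frontier)
    while (length(frontier)) {
      nxt <- unique(unlist(graph$adjacency[as.character(frontier)],
                           use.names = FALSE))
      nxt <- intersect(nxt, left)
      comp <- c(comp, nxt)
      left <- setdiff(left, nxt)
      frontier <- nxt
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Predict incipient primordium positions by golden-angle extrapolation
#'
#' The azimuth of incipient primordium i_n is the azimuth of the youngest
#' existing primordium plus `n` times the divergence angle (mod 360);
#' radially, predictions sit on the meristem region boundary.
#'
#' @param primordia data.frame from [locate_primordia()] (at least one
#'   row).
#' @param divergence divergence angle (degrees); 137.5, the golden angle,
#'   by default.
#' @param k number of incipient positions i_1..i_k to predict.
#' @param region,mesh,segmentation optional; when given, the radial
#'   position is the outermost region-cell centroid radius, otherwise 80%
#'   of the youngest primordium's radius.
#' @return data.frame with `id` (i1..ik), `n`, `azimuth`, `x`, `y`.
#' @export
predict_incipient_positions <- function(primordia, divergence = 137.5,
                                        k = 3L, region = NULL, mesh = NULL,
                                        segmentation = NULL) {
  if (is.null(primordia) || !nrow(primordia))
    stop("at least one existing primordium is required")
  youngest <- primordia[which.min(primordia$age_rank), ]
  if (!is.null(region) && !is.null(mesh) && !is.null(segmentation)) {
    cents <- cell_centroids(mesh, segmentation)
    ca <- cell_areas(mesh, segmentation)
    rc <- cents[as.character(region$cell_ids), , drop = FALSE]
    w <- ca[as.character(region$cell_ids)]
    orig <- apply(rc * w, 2L, sum) / sum(w)
    rb <- max(sqrt((rc[, 1L] - orig[1L])^2 + (rc[, 2L] - orig[2L])^2))
  } else {
    orig <- c(youngest$x, youngest$y) * 0   # fall back to azimuth frame origin
    rb <- 0.8 * sqrt(youngest$x^2 + youngest$y^2)
    orig <- c(0, 0)
  }
  n <- seq_len(k)
  az <- (youngest$azimuth + n * divergence) %% 360
  data.frame(id = paste0("i", n), n = n, azimuth = az,
             x = orig[1L] + rb * cos(az * pi / 180),
             y = orig[2L] + rb * sin(az * pi / 180))
}

#' Write per-cell and per-apex morphometrics CSVs
#'
#' @param mesh,segmentation,region,zones pipeline objects for one apex.
#' @param record the [summarize_apex()] record.
#' @param cells_csv,summary_csv output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_morphometrics <- function(mesh, segmentation, region, zones, record,
                                cells_csv = NULL, summary_csv = NULL) {
  out <- character()
  if (!is.null(cells_csv)) {
    ca <- cell_areas(mesh, segmentation)
    ids <- as.integer(names(ca))
    ring <- zones$ring[match(ids, zones$cell_id)]
    zone <- zones$zone[match(ids, zones$cell_id)]
    zone[is.na(zone)] <- "outside"
    write.csv(data.frame(cell_id = ids, area_um2 = as.numeric(ca),
                         ring = ring, zone = zone,
                         K_mean = as.numeric(region$cell_K[as.character(ids)]),
                         in_region = ids %in% region$cell_ids),
              cells_csv, row.names = FALSE)
    out <- c(out, cells_csv)
  }
  if (!is.null(summary_csv)) {
    write.csv(as.data.frame(record), summary_csv, row.names = FALSE)
    out <- c(out, summary_csv)
  }
  invisible(out)
}
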