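#' Project reporter signal onto the cellular mesh
#'
#' Extracts fluorescent signal from a depth band below the meristem
#' surface — 2-10 µm by default, immediately under the epidermal surface —
#' and projects it onto the cells: per vertex, the mean (or maximum) of
#' trilinear samples along the inward normal across the band; per cell, the
#' area-weighted mean over the cell's vertices. Vertices whose sampling ray
#' leaves the stack are flagged undefined and excluded; a cell with no
#' defined vertex gets `NA`.
#'
#' @param stack a [volume_stack()] (reporter channel).
#' @param mesh a [surface_mesh()] in the same µm frame.
#' @param segmentation a [cell_segmentation()].
#' @param band depth band (µm below the surface).
#' @param aggregate `"mean"` (default) or `"max"` along the normal.
#' @param reporter reporter name carried into the output.
#' @return object of class `signal_map`: data.frame with `cell_id`,
#'   `mean_intensity`, `n_vertices`, `defined`; attributes `band`,
#'   `aggregate`, `reporter`.
#' @export
project_signal <- function(stack, mesh, segmentation, band = c(2, 10),
                           aggregate = c("mean", "max"), reporter = "reporter") {
  aggregate <- match.arg(aggregate)
  if (band[1L] >= band[2L]) stop("band must satisfy band_min < band_max")
  vs <- stack$voxel_size
  step <- min(vs) / 2
  if (aggregate == "mean") {
    vals <- cpp_band_sample(stack$intensities, dim(stack$intensities),
                            vs["z"], vs["y"], vs["x"], stack$z_top,
                            mesh$vertices, -mesh$normals,
                            band[1L], band[2L], step)
  } else {
    depths <- seq(band[1L], band[2L], by = step)
    acc <- NULL
    for (d in depths) {
      v <- cpp_band_sample(stack$intensities, dim(stack$intensities),
                           vs["z"], vs["y"], vs["x"], stack$z_top,
                           mesh$vertices, -mesh$normals, d, d, step)
      acc <- if (is.null(acc)) v else pmax(acc, v)
    }
    vals <- acc
  }
  vlab <- vertex_labels_from_triangles(mesh, seg_labels(segmentation))
  ta <- triangle_areas(mesh)
  varea <- rep(0, nrow(mesh$vertices))
  aacc <- rowsum(rep(ta / 3, 3L), as.vector(mesh$triangles))
  varea[as.integer(rownames(aacc))] <- as.numeric(aacc)
  ids <- sort(unique(vlab[vlab > 0L]))
  ok <- !is.na(vals) & vlab > 0L
  num <- rowsum((varea * vals)[ok], vlab[ok])
  den <- rowsum(varea[ok], vlab[ok])
  cellv <- setNames(rep(NA_real_, length(ids)), as.character(ids))
  cellv[rownames(num)] <- as.numeric(num) / as.numeric(den)
  nv <- table(factor(vlab[vlab > 0L], levels = ids))
  out <- data.frame(cell_id = ids, mean_intensity = as.numeric(cellv),
                    n_vertices = as.integer(nv),
                    defined = !is.na(as.numeric(cellv)))
  structure(out, band = band, aggregate = aggregate, reporter = reporter,
            class = c("signal_map", "data.frame"))
}

#' Render a per-cell heat map
#'
#' Top-down orthographic rendering of per-cell scalar values (cell area,
#' reporter intensity, ...) as a PNG, plus an optional per-triangle colored
#' PLY. The color range is either given or taken from the data min-max and
#' recorded in the returned metadata. Rendering identical inputs is
#' byte-identical.
#'
#' @param values named numeric vector (names = cell labels) or a
#'   [project_signal()] map.
#' @param mesh a [surface_mesh()].
#' @param segmentation a [cell_segmentation()].
#' @param png_path output PNG path.
#' @param ply_path optional colored-PLY path.
#' @param colormap vector of colors (monotone low-to-high ramp).
#' @param range fixed color range `c(lo, hi)`, or `NULL` for data min-max.
#' @param pixel rendering pixel size (µm).
#' @return invisibly, list with `png`, `ply`, `range`, `colormap_n`.
#' @export
render_heatmap <- function(values, mesh, segmentation, png_path,
                           ply_path = NULL,
                           colormap = grDevices::hcl.colors(256, "viridis"),
                           range = NULL, pixel = 0.5) {
  if (inherits(values, "signal_map"))
    values <- setNames(values$mean_intensity, values$cell_id)
  if (!length(values)) stop("empty value map")
  tri_lab <- seg_labels(segmentation)
  vals_tri <- values[as.character(tri_lab)]
  if (is.null(range)) range <- range(values, na.rm = TRUE)
  span <- if (diff(range) > 0) diff(range) else 1
  ncol_ <- length(colormap)
  idx_tri <- pmin(ncol_, pmax(1L, 1L + as.integer(
    floor((vals_tri - range[1L]) / span * (ncol_ - 1L) + 0.5))))
  # rasterize: nearest labeled vertex in xy
  V <- mesh$vertices
  xr <- range(V[, 1L]); yr <- range(V[, 2L])
  nxp <- max(2L, as.integer(ceiling(diff(xr) / pixel)) + 1L)
  nyp <- max(2L, as.integer(ceiling(diff(yr) / pixel)) + 1L)
  px <- xr[1L] + (seq_len(nxp) - 1L) * pixel
  py <- yr[1L] + (seq_len(nyp) - 1L) * pixel
  pts <- cbind(rep(px, each = nyp), rep(py, times = nxp), 0)
  nn <- cpp_nearest2w(pts, cbind(V[, 1L], V[, 2L], 0),
                      numeric(nrow(V)), max(4 * pixel, 2))
  vlab <- vertex_labels_from_triangles(mesh, tri_lab)
  plab <- vlab[nn$idx]
  pval <- values[as.character(plab)]
  pidx <- pmin(ncol_, pmax(1L, 1L + as.integer(
    floor((pval - range[1L]) / span * (ncol_ - 1L) + 0.5))))
  rgb_ <- col2rgb(colormap) / 255
  img <- array(0, c(nyp, nxp, 3L))
  valid <- !is.na(pidx) & plab > 0L
  for (ch in 1:3) {
    m <- matrix(0, nyp, nxp)
    m[valid] <- rgb_[ch, pidx[valid]]
    img[, , ch] <- m[rev(seq_len(nyp)), ]   # image y up
  }
  png::writePNG(img, png_path)
  if (!is.null(ply_path)) {
    fc <- t(col2rgb(colormap))[ifelse(is.na(idx_tri), 1L, idx_tri), ,
                               drop = FALSE]
    write_ply(mesh, ply_path, face_labels = tri_lab, face_colors = fc)
  }
  invisible(list(png = png_path, ply = ply_path, range = range,
                 colormap_n = ncol_))
}

#' Write a signal map as CSV
#' @param map a [project_signal()] map.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_signal_map <- function(map, path) {
  band <- attr(map, "band")
  df <- data.frame(cell_id = map$cell_id, reporter = attr(map, "reporter"),
                   mean_intensity = map$mean_intensity,
                   band_min = band[1L], band_max = band[2L],
                   aggregate = attr(map, "aggregate"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
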