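#' Confocal-like image stack in physical units
#'
#' A 3D scalar intensity array in (z, y, x) axis order with voxel spacing in
#' µm. Slice 1 is the top of the stack; the physical z of slice `i` is
#' `z_top - (i - 1) * voxel_size["z"]`. Lateral coordinates are
#' `x = (ix - 1) * voxel_size["x"]`, `y = (iy - 1) * voxel_size["y"]`
#' (0-based grid, µm).
#'
#' @param intensities 3D numeric array, dim = (nz, ny, nx).
#' @param voxel_size length-3 numeric `(z, y, x)` spacing in µm; the z step
#'   defaults to 0.4 µm, the acquisition step of the stacks this pipeline
#'   is designed for.
#' @param z_top physical z (µm) of slice 1.
#' @return object of class `volume_stack`.
#' @export
volume_stack <- function(intensities, voxel_size = c(0.4, 0.5, 0.5),
                         z_top = (dim(intensities)[1L] - 1L) * voxel_size[1L]) {
  stopifnot(length(dim(intensities)) == 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive numbers (z, y, x)")
  structure(list(intensities = intensities,
                 voxel_size = setNames(voxel_size, c("z", "y", "x")),
                 z_top = z_top),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("volume_stack: %d x %d x %d (z,y,x), voxel %.2f x %.2f x %.2f um\n",
              d[1L], d[2L], d[3L], x$voxel_size[1L], x$voxel_size[2L],
              x$voxel_size[3L]))
  invisible(x)
}

#' Write a stack as multi-page TIFF
#'
#' One page per z slice (32-bit float). Intensities are rescaled to `[0, 1]`
#' for storage; the scale factor, voxel sizes and `z_top` are recorded in a
#' JSON sidecar (`<path>.json`) so that [read_stack_tiff()] restores the
#' stack exactly.
#'
#' @param stack a [volume_stack()].
#' @param path output .tif path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  arr <- stack$intensities
  mx <- max(arr, 1e-12)
  mn <- min(arr, 0)
  pages <- lapply(seq_len(dim(arr)[1L]),
                  function(i) (arr[i, , ] - mn) / (mx - mn))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size = as.numeric(stack$voxel_size),
                            z_top = stack$z_top, scale_max = mx,
                            scale_min = mn),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack written by [write_stack_tiff()]
#' @param path .tif path.
#' @return a [volume_stack()].
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::fromJSON(sidecar) else NULL
  nz <- length(pages)
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  arr <- array(0, c(nz, ny, nx))
  for (i in seq_len(nz)) arr[i, , ] <- pages[[i]]
  if (!is.null(meta)) {
    arr <- arr * (meta$scale_max - meta$scale_min) + meta$scale_min
    volume_stack(arr, voxel_size = meta$voxel_size, z_top = meta$z_top)
  } else {
    volume_stack(arr, voxel_size = c(0.4, 0.5, 0.5))
  }
}
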