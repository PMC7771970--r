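#' Write a surface mesh to PLY
#'
#' Writes binary little-endian (default) or ASCII PLY. Per-vertex scalar
#' properties (e.g. `gaussian_curvature`) are written as float properties;
#' per-face cell labels as an int property `cell_label`; per-face colors as
#' uchar `red`/`green`/`blue`.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @param vertex_props named list of numeric vectors (length = n vertices).
#' @param face_labels optional integer vector (length = n triangles),
#'   written as property `cell_label`.
#' @param face_colors optional n x 3 matrix of 0-255 RGB values.
#' @param binary write binary little-endian (TRUE) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, vertex_props = list(), face_labels = NULL,
                      face_colors = NULL, binary = TRUE) {
  V <- mesh$vertices; F <- mesh$triangles
  nv <- nrow(V); nf <- nrow(F)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment meristemorph surface mesh",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("property float %s", names(vertex_props)),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           if (!is.null(face_labels)) "property int cell_label",
           if (!is.null(face_colors)) c("property uchar red",
                                        "property uchar green",
                                        "property uchar blue"),
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  vmat <- cbind(V, do.call(cbind, lapply(vertex_props, as.numeric)))
  if (binary) {
    writeBin(as.numeric(t(vmat)), con, size = 4L, endian = "little")
    stride <- 13L + (if (!is.null(face_labels)) 4L else 0L) +
      (if (!is.null(face_colors)) 3L else 0L)
    block <- matrix(as.raw(0L), nrow = stride, ncol = nf)
    block[1L, ] <- as.raw(3L)
    idx <- writeBin(as.integer(t(F - 1L)), raw(), size = 4L, endian = "little")
    block[2:13, ] <- matrix(idx, nrow = 12L)
    off <- 13L
    if (!is.null(face_labels)) {
      lb <- writeBin(as.integer(face_labels), raw(), size = 4L, endian = "little")
      block[off + (1:4), ] <- matrix(lb, nrow = 4L)
      off <- off + 4L
    }
    if (!is.null(face_colors))
      block[off + (1:3), ] <- matrix(as.raw(t(round(face_colors))), nrow = 3L)
    writeBin(as.vector(block), con)
  } else {
    writeLines(apply(vmat, 1L, function(r) paste(format(r, digits = 9L, trim = TRUE),
                                                 collapse = " ")), con)
    fl <- cbind(3L, F - 1L)
    if (!is.null(face_labels)) fl <- cbind(fl, as.integer(face_labels))
    if (!is.null(face_colors)) fl <- cbind(fl, round(face_colors))
    writeLines(apply(fl, 1L, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Read a PLY surface mesh
#'
#' Supports ASCII and binary little-endian PLY with float/double/int vertex
#' properties and triangular faces (`vertex_indices` list plus optional
#' scalar face properties such as `cell_label`).
#'
#' @param path PLY file.
#' @return a [surface_mesh()] with attributes `vertex_props` (data.frame of
#'   extra vertex properties) and `face_props` (data.frame, e.g.
#'   `cell_label`).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("truncated PLY header")
    lines <- c(lines, ln)
    if (ln == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format ", lines, value = TRUE)[1L])
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt)) stop("unsupported PLY format: ", fmt)
  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L, short = 2L,
             ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L, uint = 4L,
             int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
             double = 8L, float64 = 8L)
  elems <- list(); cur <- NULL
  for (ln in lines) {
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      cur <- tok[2L]
      elems[[cur]] <- list(n = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(cur)) {
      p <- if (tok[2L] == "list")
        list(name = tok[5L], type = tok[4L], list = TRUE, count_type = tok[3L])
      else list(name = tok[3L], type = tok[2L], list = FALSE)
      elems[[cur]]$props <- c(elems[[cur]]$props, list(p))
    }
  }
  ve <- elems[["vertex"]]; fe <- elems[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY lacks vertex or face element")
  vnames <- vapply(ve$props, `[[`, "", "name")
  if (binary) {
    vsz <- sizes[vapply(ve$props, `[[`, "", "type")]
    if (length(unique(vsz)) != 1L)
      stop("mixed vertex property sizes not supported")
    israw <- readBin(con, "raw", n = ve$n * sum(vsz))
    vdat <- matrix(readBin(israw, "numeric", n = ve$n * length(vsz),
                           size = vsz[1L], endian = "little"),
                   ncol = length(vsz), byrow = TRUE)
    colnames(vdat) <- vnames
    fprops <- fe$props
    stopifnot(fprops[[1L]]$list)
    cstride <- sizes[fprops[[1L]]$count_type]
    istride <- 3L * sizes[fprops[[1L]]$type]
    extra <- fprops[-1L]
    esz <- if (length(extra)) sizes[vapply(extra, `[[`, "", "type")] else integer()
    stride <- cstride + istride + sum(esz)
    fraw <- matrix(readBin(con, "raw", n = fe$n * stride), nrow = stride)
    cnt <- as.integer(fraw[1L, ])
    if (any(cnt != 3L)) stop("non-triangular PLY faces not supported")
    F <- matrix(readBin(as.vector(fraw[cstride + seq_len(istride), , drop = FALSE]),
                        "integer", n = 3L * fe$n, size = sizes[fprops[[1L]]$type],
                        endian = "little"),
                ncol = 3L, byrow = TRUE) + 1L
    fdat <- list()
    off <- cstride + istride
    for (k in seq_along(extra)) {
      what <- if (extra[[k]]$type %in% c("float", "float32", "double", "float64"))
        "numeric" else "integer"
      fdat[[extra[[k]]$name]] <-
        readBin(as.vector(fraw[off + seq_len(esz[k]), , drop = FALSE]), what,
                n = fe$n, size = esz[k], endian = "little",
                signed = !(esz[k] == 1L))
      off <- off + esz[k]
    }
  } else {
    txt <- readLines(con)
    vdat <- matrix(scan(text = txt[seq_len(ve$n)], quiet = TRUE),
                   ncol = length(vnames), byrow = TRUE)
    colnames(vdat) <- vnames
    frows <- txt[ve$n + seq_len(fe$n)]
    fmatr <- matrix(scan(text = frows, quiet = TRUE),
                    nrow = fe$n, byrow = TRUE)
    if (any(fmatr[, 1L] != 3)) stop("non-triangular PLY faces not supported")
    F <- fmatr[, 2:4, drop = FALSE] + 1L
    extra <- fe$props[-1L]
    fdat <- list()
    for (k in seq_along(extra))
      fdat[[extra[[k]]$name]] <- fmatr[, 4L + k]
  }
  mesh <- surface_mesh(vdat[, c("x", "y", "z"), drop = FALSE], F)
  other <- setdiff(vnames, c("x", "y", "z"))
  attr(mesh, "vertex_props") <- as.data.frame(vdat[, other, drop = FALSE])
  attr(mesh, "face_props") <- as.data.frame(fdat)
  mesh
}

#' Read a Wavefront OBJ mesh
#' @param path OBJ file.
#' @return a [surface_mesh()].
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  V <- matrix(scan(text = sub("^v ", "", vl), quiet = TRUE), ncol = 3L,
              byrow = TRUE)
  ftok <- strsplit(trimws(sub("^f ", "", fl)), "\\s+")
  F <- t(vapply(ftok, function(t) as.integer(sub("/.*$", "", t[1:3])),
                integer(3L)))
  surface_mesh(V, F)
}

#' Write a Wavefront OBJ mesh
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1L],
                     mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1L],
                     mesh$triangles[, 2L], mesh$triangles[, 3L]), con)
  invisible(path)
}
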