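#' Stage presets for the synthetic apex generator
#'
#' Named parameter sets emulating shoot apical meristems at the
#' developmental stages the pipeline quantifies: a vegetative SAM, the
#' enlarged domed (transition) SAM, a mature inflorescence SAM, and two
#' qualitative mutant-like variants (`ft_tsf_like`: lateral cap expansion
#' without doming; `narrow_meristem`: reduced cap width at unchanged cell
#' size). The vegetative/domed pair is calibrated so that, on ground truth,
#' domed/vegetative meristem area = 4.0, region cell number = 3.5x, and
#' median cell area = 1.8x — the fold-changes that characterize doming at
#' floral transition.
#'
#' Because meristem area is the sum of its cell areas, the triple
#' (area 4.0x, cells 3.5x, median area 1.8x) forces the vegetative
#' cell-area distribution to be right-skewed (median below mean): the
#' generator realizes it with three radial size blocks (small cells
#' centrally, median-sized cells in a middle annulus, larger cells
#' peripherally), while the domed preset is near-uniform.
#'
#' @param name one of `"vegetative"`, `"domed"`, `"inflorescence"`,
#'   `"ft_tsf_like"`, `"narrow_meristem"`.
#' @param ... named overrides of individual preset fields.
#' @return object of class `apex_preset`: a list with fields `name`,
#'   `dome_radius` (cap footprint radius, µm, solved from the nominal area
#'   and dome height), `dome_height` (µm), `meristem_cap_area` (µm²),
#'   `n_cells` (nominal region cell count), `median_cell_area` (µm²),
#'   `n_primordia`, `divergence_angle` (degrees), `primordium_radius` (µm),
#'   `primordium_height` (µm), `cell_area_cv`, `noise_sd`.
#' @export
apex_preset <- function(name = c("vegetative", "domed", "inflorescence",
                                 "ft_tsf_like", "narrow_meristem"), ...) {
  name <- match.arg(name)
  # vegetative anchors; domed = 4.0x area, 3.5x cells, 1.8x median cell area
  veg_area <- 4000; veg_n <- 240L
  veg_median <- (4 / (3.5 * 1.8)) * veg_area / veg_n   # 10.582 um^2
  base <- switch(name,
    vegetative = list(meristem_cap_area = veg_area, n_cells = veg_n,
                      median_cell_area = veg_median, dome_height = 8,
                      n_primordia = 3L, primordium_radius = 5,
                      primordium_height = 3),
    domed = list(meristem_cap_area = 4 * veg_area, n_cells = 840L,
                 median_cell_area = 1.8 * veg_median, dome_height = 35,
                 n_primordia = 3L, primordium_radius = 5,
                 primordium_height = 6),
    inflorescence = list(meristem_cap_area = 3 * veg_area, n_cells = 630L,
                         median_cell_area = 1.8 * veg_median,
                         dome_height = 22, n_primordia = 5L,
                         primordium_radius = 5, primordium_height = 5),
    ft_tsf_like = list(meristem_cap_area = 2.5 * veg_area, n_cells = 600L,
                       median_cell_area = 2.5 * veg_area / 600,
                       dome_height = 8, n_primordia = 3L,
                       primordium_radius = 5, primordium_height = 2),
    narrow_meristem = list(meristem_cap_area = 0.6 * veg_area, n_cells = 144L,
                           median_cell_area = veg_median, dome_height = 8,
                           n_primordia = 3L, primordium_radius = 4,
                           primordium_height = 3))
  p <- modifyList(c(base, list(name = name, divergence_angle = 137.5,
                               cell_area_cv = 0.25, noise_sd = 2)),
                  list(...))
  if (p$meristem_cap_area <= 0 || p$median_cell_area <= 0 || p$dome_height <= 0)
    stop("preset areas and dome height must be positive")
  p$dome_radius <- solve_cap_width(p$meristem_cap_area, p$dome_height)
  structure(p, class = "apex_preset")
}

#' @export
print.apex_preset <- function(x, ...) {
  cat(sprintf(paste0("apex_preset '%s': cap area %.0f um^2 (footprint radius",
                     " %.1f um, height %g um), %d cells, median cell area",
                     " %.2f um^2, %d primordia\n"),
              x$name, x$meristem_cap_area, x$dome_radius, x$dome_height,
              x$n_cells, x$median_cell_area, x$n_primordia))
  invisible(x)
}

# The dome is a Gaussian profile z = h exp(-r^2 / 2 s^2); its Gaussian
# curvature changes sign exactly at r = s. Solve s so that the surface area
# inside r = s equals the nominal meristem cap area.
solve_cap_width <- function(area, h) {
  g <- function(s) {
    f <- function(u) 2 * pi * u * sqrt(1 + (h / s)^2 * u^2 * exp(-u^2))
    s^2 * stats::integrate(f, 0, 1, rel.tol = 1e-10)$value - area
  }
  s0 <- sqrt(area / pi)
  stats::uniroot(g, c(0.2 * s0, 1.05 * s0), tol = 1e-8)$root
}

# cumulative pure-dome surface area A(r) and its inverse, as approxfuns
dome_area_tables <- function(sigma, h, rmax, step = 0.05) {
  rs <- seq(0, rmax, by = step)
  zp <- -h * rs / sigma^2 * exp(-rs^2 / (2 * sigma^2))
  f <- 2 * pi * rs * sqrt(1 + zp^2)
  cum <- c(0, cumsum((f[-1L] + f[-length(f)]) / 2 * diff(rs)))
  list(A_of_r = stats::approxfun(rs, cum, rule = 2L),
       r_of_A = stats::approxfun(cum, rs, rule = 2L))
}

# run expr with a local RNG state; restores the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

surface_height <- function(xy, center, sigma, h, bumps) {
  dx <- xy[, 1L] - center[1L]; dy <- xy[, 2L] - center[2L]
  z <- h * exp(-(dx^2 + dy^2) / (2 * sigma^2))
  if (!is.null(bumps) && nrow(bumps)) {
    for (k in seq_len(nrow(bumps))) {
      bx <- xy[, 1L] - bumps$x[k]; by <- xy[, 2L] - bumps$y[k]
      z <- z + bumps$hp[k] * exp(-(bx^2 + by^2) / (2 * bumps$sp[k]^2))
    }
  }
  z
}

#' Analytic Gaussian curvature of a synthetic scene's surface
#'
#' Closed-form K of the generating height field (dome plus primordium
#' bumps), used as scene ground truth when validating curvature estimators
#' and region delimitation.
#'
#' @param scene a scene from [generate_apex_scene()].
#' @param xy n x 2 matrix of absolute (x, y) positions (µm).
#' @return numeric vector of K (µm^-2).
#' @export
analytic_gaussian_curvature <- function(scene, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2L)
  s <- scene$surface
  comps <- rbind(data.frame(x = s$center[1L], y = s$center[2L],
                            sp = s$sigma, hp = s$h),
                 if (nrow(s$bumps)) s$bumps[, c("x", "y", "sp", "hp")])
  zx <- zy <- zxx <- zyy <- zxy <- rep(0, nrow(xy))
  for (k in seq_len(nrow(comps))) {
    ux <- xy[, 1L] - comps$x[k]; uy <- xy[, 2L] - comps$y[k]
    s2 <- comps$sp[k]^2
    E <- comps$hp[k] * exp(-(ux^2 + uy^2) / (2 * s2))
    zx <- zx - ux / s2 * E
    zy <- zy - uy / s2 * E
    zxx <- zxx + E * (ux^2 / s2^2 - 1 / s2)
    zyy <- zyy + E * (uy^2 / s2^2 - 1 / s2)
    zxy <- zxy + E * ux * uy / s2^2
  }
  (zxx * zyy - zxy^2) / (1 + zx^2 + zy^2)^2
}

#' Generate a synthetic apex scene with full ground truth
#'
#' Builds a complete synthetic shoot apex: a Gaussian dome (its Gaussian
#' curvature changes sign exactly on the circle `r = dome_radius`, the
#' ground-truth meristem boundary), primordium bumps at successive golden
#' angle positions with ages increasing away from the youngest, an
#' epidermal tessellation (annular rings of near-square sector cells with
#' prescribed per-cell areas) whose within-region median cell area matches
#' the preset exactly, and a cell-wall-stain
#' image stack rendered from the tessellation. Everything downstream of the
#' generator (surface extraction, segmentation, curvature, delimitation,
#' statistics) can be validated against the returned ground truth.
#'
#' @param preset an [apex_preset()].
#' @param seed integer >= 0; identical (preset, seed) pairs give
#'   bit-identical scenes.
#' @param pixel_xy lateral grid spacing of mesh and stack (µm).
#' @param z_step stack slice spacing (µm); 0.4 by default.
#' @param primordium_offset bump center placed at
#'   `dome_radius + primordium_offset * bump_width`; lowering it until a
#'   bump touches the dome is an error (bump placement fails loudly).
#' @param wall_amplitude,coat_amplitude intensity of anticlinal wall ridges
#'   and of the outer periclinal wall coat.
#' @param l1_thickness,coat_thickness,wall_width depth extent of wall
#'   signal, of the surface coat, and lateral wall half-width (µm).
#' @return object of class `synthetic_scene` with elements `mesh`
#'   ([surface_mesh()]), `true_segmentation` ([cell_segmentation()]),
#'   `true_region` (cell ids), `true_central_cell`, `true_primordia`
#'   (data.frame), `true_incipient` (data.frame), `wall_stack`
#'   ([volume_stack()]), `reporter_stacks` (named list, empty until
#'   [make_reporter_field()] is used), `params`, `seed`, plus generator
#'   internals (`surface`, `grid`, `rings`, `H`, `a_target`).
#' @export
generate_apex_scene <- function(preset, seed, pixel_xy = 0.5, z_step = 0.4,
                                primordium_offset = 3,
                                wall_amplitude = 100, coat_amplitude = 60,
                                l1_thickness = 5, coat_thickness = 0.8,
                                wall_width = 0.35) {
  if (!inherits(preset, "apex_preset")) stop("preset must be an apex_preset")
  if (seed < 0) stop("seed must be >= 0")
  with_seed(seed, {
    sigma <- preset$dome_radius
    h <- preset$dome_height
    # --- primordia: golden-angle spiral, ages increasing with k ---
    np <- preset$n_primordia
    phi0 <- runif(1, 0, 360)
    bumps <- if (np > 0L) {
      k <- seq_len(np)
      # clear size ordering with age, tapering so old bumps stay compact
      grow <- 1 + 0.3 * pmin(k - 1, 2) + 0.1 * pmax(k - 3, 0)
      sp <- preset$primordium_radius * grow
      hp <- preset$primordium_height * grow
      R <- sigma + primordium_offset * sp
      if (any(R - 2 * sp <= sigma))
        stop("primordium bump overlaps the meristem summit dome; ",
             "increase primordium_offset or reduce primordium_radius")
      az <- (phi0 - (k - 1) * preset$divergence_angle) %% 360
      data.frame(id = paste0("P", k), age_rank = k, azimuth = az,
                 R = R, sp = sp, hp = hp,
                 x = R * cos(az * pi / 180), y = R * sin(az * pi / 180))
    } else data.frame(id = character(), age_rank = integer(),
                      azimuth = numeric(), R = numeric(), sp = numeric(),
                      hp = numeric(), x = numeric(), y = numeric())
    if (nrow(bumps)) {
      zb <- h * exp(-bumps$R^2 / (2 * sigma^2)) + bumps$hp
      if (any(zb >= 0.95 * h))
        stop("primordium bump would rival the dome summit; ",
             "reduce primordium_height")
    }
    r_edge <- max(sigma, if (nrow(bumps)) max(bumps$R + 2.2 * bumps$sp) else 0) + 2
    half <- ceiling(r_edge / pixel_xy) * pixel_xy
    nx <- ny <- as.integer(2 * round(half / pixel_xy) + 1)
    center <- c(half, half)
    bumps$x <- bumps$x + center[1L]; bumps$y <- bumps$y + center[2L]

    # --- height field and truth mesh ---
    xs <- (seq_len(nx) - 1) * pixel_xy
    ys <- (seq_len(ny) - 1) * pixel_xy
    gx <- rep(xs, each = ny); gy <- rep(ys, times = nx)
    Hv <- surface_height(cbind(gx, gy), center, sigma, h, bumps)
    H <- matrix(Hv, ny, nx)
    mesh <- heightmap_mesh(H, dx = pixel_xy, dy = pixel_xy)

    # --- cell-area blocks inside the region ---
    A <- preset$meristem_cap_area
    N <- as.integer(preset$n_cells)
    m <- preset$median_cell_area
    mu <- A / N
    if (abs(m - mu) <= 0.05 * mu) {
      blocks <- data.frame(n = N, a = mu)
    } else {
      # three radial blocks with the 40% median block in the middle, so the
      # combined median sits at the center of the median block and is robust
      # to per-cell scatter and boundary churn
      nmed <- as.integer(round(0.4 * N))
      nlo <- as.integer(round(0.3 * N))
      nhi <- N - nmed - nlo
      if (m <= mu) {
        alo <- 0.6 * m
        ahi <- (A - nmed * m - nlo * alo) / nhi
        if (ahi <= m)
          stop("median_cell_area incompatible with cap area and cell count")
      } else {
        ahi <- 1.67 * m
        alo <- (A - nmed * m - nhi * ahi) / nlo
        if (alo <= 0 || alo >= m)
          stop("median_cell_area incompatible with cap area and cell count")
      }
      blocks <- data.frame(n = c(nlo, nmed, nhi), a = c(alo, m, ahi))
    }
    cv <- preset$cell_area_cv
    # jittered per-cell target areas; block totals preserved exactly, and
    # the median block kept tight (it anchors the calibration)
    a_region <- numeric(0)
    for (b in seq_len(nrow(blocks))) {
      cvb <- if (nrow(blocks) == 3L && b == 2L) cv / 3 else cv
      jf <- pmin(2, pmax(0.4, 1 + rnorm(blocks$n[b], 0, cvb)))
      a_region <- c(a_region, blocks$a[b] * blocks$n[b] * jf / sum(jf))
    }
    rmax <- sqrt(2) * half + 2
    tab <- dome_area_tables(sigma, h, rmax)
    a_region <- a_region * tab$A_of_r(sigma) / sum(a_region)
    # flank cells (outside the region) out to the mesh corners
    a_flank <- 1.5 * mu
    flank_area <- tab$A_of_r(rmax) - tab$A_of_r(sigma)
    n_flank <- max(1L, as.integer(ceiling(flank_area / a_flank)))
    jf <- pmin(2, pmax(0.4, 1 + rnorm(n_flank, 0, cv)))
    a_all <- c(a_region, flank_area * jf / sum(jf))
    n_cells <- length(a_all)

    # --- annular ring/sector tessellation with exact per-cell areas ---
    # cells are laid out radially (in the equal-area coordinate of the pure
    # dome) in rings of near-square sectors; each cell gets an angular width
    # proportional to its target area, so per-cell areas are exact up to
    # pixelation of the triangle grid
    ring_rin <- ring_rout <- ring_phi <- numeric(0)
    ring_start <- ring_n <- integer(0)
    cell_ring <- integer(n_cells)
    i <- 1L; u <- 0; ring <- 0L
    while (i <= n_cells) {
      ring <- ring + 1L
      r_in <- tab$r_of_A(u)
      if (i == 1L) {
        n_r <- 1L                        # the central cell is a disk
      } else {
        w_r <- sqrt(a_all[i])            # aim for square-ish sectors
        S_g <- tab$A_of_r(r_in + w_r) - u
        n_r <- max(3L, as.integer(round(S_g / a_all[i])))
        n_r <- min(n_r, n_cells - i + 1L)
        if (i <= N && i + n_r - 1L > N)  # rings never span the region edge
          n_r <- N - i + 1L
      }
      sel <- i:(i + n_r - 1L)
      S <- sum(a_all[sel])
      ring_rin[ring] <- r_in
      ring_rout[ring] <- tab$r_of_A(u + S)
      ring_phi[ring] <- runif(1, 0, 2 * pi)
      ring_start[ring] <- i
      ring_n[ring] <- n_r
      cell_ring[sel] <- ring
      u <- u + S
      i <- i + n_r
    }
    n_rings <- ring
    ring_cuts <- ring_rout
    ring_cuts[n_rings] <- rmax + 1       # numeric safety at the outer rim
    sector_widths <- lapply(seq_len(n_rings), function(k) {
      sel <- ring_start[k] + seq_len(ring_n[k]) - 1L
      2 * pi * a_all[sel] / sum(a_all[sel])
    })

    # label lookup for arbitrary (x, y): ring by radius, sector by angle
    ring_sector_labels <- function(px, py) {
      rr <- sqrt((px - center[1L])^2 + (py - center[2L])^2)
      th <- atan2(py - center[2L], px - center[1L]) %% (2 * pi)
      kk <- findInterval(rr, ring_cuts) + 1L
      kk[kk > n_rings] <- n_rings
      lab <- integer(length(rr))
      for (k in unique(kk)) {
        selp <- which(kk == k)
        if (ring_n[k] == 1L) { lab[selp] <- ring_start[k]; next }
        cuts <- cumsum(sector_widths[[k]])
        rel <- (th[selp] - ring_phi[k]) %% (2 * pi)
        idx <- findInterval(rel, c(0, cuts[-length(cuts)]))
        lab[selp] <- ring_start[k] + idx - 1L
      }
      lab
    }
    ta <- triangle_areas(mesh)
    tc <- (mesh$vertices[mesh$triangles[, 1L], , drop = FALSE] +
             mesh$vertices[mesh$triangles[, 2L], , drop = FALSE] +
             mesh$vertices[mesh$triangles[, 3L], , drop = FALSE]) / 3
    tri_lab <- ring_sector_labels(tc[, 1L], tc[, 2L])
    segm <- cell_segmentation(tri_lab)
    region_ids <- seq_len(N)
    central <- 1L

    # --- wall-stain stack: ridges on ring and sector boundaries ---
    r_v <- sqrt((gx - center[1L])^2 + (gy - center[2L])^2)
    th_v <- atan2(gy - center[2L], gx - center[1L]) %% (2 * pi)
    kv <- findInterval(r_v, ring_cuts) + 1L
    kv[kv > n_rings] <- n_rings
    slope <- sqrt(1 + (h * r_v / sigma^2 * exp(-r_v^2 / (2 * sigma^2)))^2)
    d_in <- r_v - ring_rin[kv]
    d_in[ring_rin[kv] <= 0] <- Inf     # the central disk has no inner wall
    d_ring <- pmin(d_in, pmax(ring_rout[kv] - r_v, 0)) * slope
    d_sec <- rep(Inf, length(r_v))
    for (k in unique(kv)) {
      if (ring_n[k] == 1L) next
      selp <- which(kv == k)
      cuts <- c(0, cumsum(sector_widths[[k]]))
      rel <- (th_v[selp] - ring_phi[k]) %% (2 * pi)
      idx <- findInterval(rel, cuts[-length(cuts)])
      off <- rel - cuts[idx]
      d_sec[selp] <- r_v[selp] * pmin(off, cuts[idx + 1L] - rel)
    }
    d_wall <- pmin(d_ring, d_sec)
    B <- matrix(exp(-d_wall^2 / (2 * wall_width^2)), ny, nx)
    # anticlinal walls run perpendicular to the surface: at depth d below a
    # surface point, the wall sheet is laterally displaced along the height
    # gradient, and the physical (along-normal) depth is the vertical depth
    # over sqrt(1 + |grad H|^2)
    Hx <- (H[, c(2:nx, nx)] - H[, c(1, 1:(nx - 1L))]) / (2 * pixel_xy)
    Hy <- (H[c(2:ny, ny), ] - H[c(1, 1:(ny - 1L)), ]) / (2 * pixel_xy)
    g2 <- Hx^2 + Hy^2
    sl <- sqrt(1 + g2)
    z_top <- max(H) + 1
    z_pad <- 12                       # keep depth bands inside the stack
    nz <- as.integer(floor((z_top + z_pad) / z_step)) + 1L
    arr <- array(0, c(nz, ny, nx))
    iy_g <- rep(seq_len(ny), times = nx)
    ix_g <- rep(seq_len(nx), each = ny)
    for (i in seq_len(nz)) {
      zi <- z_top - (i - 1L) * z_step
      depth <- H - zi
      dn <- depth / sl
      sel <- which(dn >= 0 & dn <= l1_thickness)
      if (!length(sel)) next
      sli <- matrix(0, ny, nx)
      fj <- ix_g[sel] - (depth[sel] * Hx[sel] / (1 + g2[sel])) / pixel_xy
      fi <- iy_g[sel] - (depth[sel] * Hy[sel] / (1 + g2[sel])) / pixel_xy
      sli[sel] <- wall_amplitude * bilinear_lookup(B, fi, fj)
      cc <- dn >= 0 & dn <= coat_thickness
      sli[cc] <- sli[cc] + coat_amplitude
      arr[i, , ] <- sli
    }
    if (preset$noise_sd > 0)
      arr[] <- pmax(0, arr + rnorm(length(arr), 0, preset$noise_sd))
    wall <- volume_stack(arr, voxel_size = c(z_step, pixel_xy, pixel_xy),
                         z_top = z_top)

    # --- incipient primordium truth (next golden-angle positions) ---
    incip <- if (nrow(bumps)) {
      n_i <- seq_len(3L)
      azi <- (bumps$azimuth[1L] + n_i * preset$divergence_angle) %% 360
      data.frame(id = paste0("i", n_i), n = n_i, azimuth = azi,
                 x = center[1L] + sigma * cos(azi * pi / 180),
                 y = center[2L] + sigma * sin(azi * pi / 180))
    } else data.frame(id = character(), n = integer(), azimuth = numeric(),
                      x = numeric(), y = numeric())
    prim_truth <- if (nrow(bumps)) {
      data.frame(id = bumps$id, age_rank = bumps$age_rank,
                 azimuth = bumps$azimuth, x = bumps$x, y = bumps$y,
                 z = surface_height(cbind(bumps$x, bumps$y), center, sigma,
                                    h, bumps))
    } else data.frame(id = character(), age_rank = integer(),
                      azimuth = numeric(), x = numeric(), y = numeric(),
                      z = numeric())

    structure(list(mesh = mesh, true_segmentation = segm,
                   true_region = region_ids, true_central_cell = central,
                   true_primordia = prim_truth, true_incipient = incip,
                   wall_stack = wall, reporter_stacks = list(),
                   params = preset, seed = as.integer(seed),
                   surface = list(center = center, sigma = sigma, h = h,
                                  bumps = bumps, r_edge = r_edge),
                   grid = list(pixel_xy = pixel_xy, z_step = z_step,
                               nx = nx, ny = ny, z_top = z_top),
                   rings = list(r_in = ring_rin, r_out = ring_rout,
                                phi = ring_phi, start = ring_start,
                                n = ring_n,
                                sector_widths = sector_widths),
                   H = H, a_target = a_all),
              class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf(paste0("synthetic_scene '%s' (seed %d): %d cells ",
                     "(%d in region), %d primordia\n"),
              x$params$name, x$seed, length(unique(seg_labels(x$true_segmentation))),
              length(x$true_region), nrow(x$true_primordia)))
  invisible(x)
}

#' Render a reporter-signal volume for a synthetic scene
#'
#' Emulates fluorescent reporter expression confined to a depth band below
#' the epidermal surface: `pz_patches` places patches at the ground-truth
#' incipient primordium positions on the periphery of the meristem,
#' `abaxial_primordia` marks the abaxial (outward-facing) side of each
#' primordium bump, `uniform` fills the whole band, `none` is an all-zero
#' stack.
#'
#' @param scene a [generate_apex_scene()] scene.
#' @param pattern one of `"pz_patches"`, `"abaxial_primordia"`,
#'   `"uniform"`, `"none"`.
#' @param amplitude nominal intensity of the expression domain.
#' @param band depth band (µm below the surface) holding the signal.
#' @param noise_sd Gaussian noise sd; defaults to the preset's.
#' @param noise_seed RNG seed for the noise field.
#' @return a [volume_stack()]; for `pz_patches` and `abaxial_primordia` the
#'   attribute `footprint` holds the ground-truth lateral mask (ny x nx).
#' @export
make_reporter_field <- function(scene, pattern, amplitude = 100,
                                band = c(2, 10), noise_sd = NULL,
                                noise_seed = scene$seed + 1000L) {
  patterns <- c("pz_patches", "abaxial_primordia", "uniform", "none")
  if (!is.character(pattern) || length(pattern) != 1L || !pattern %in% patterns)
    stop("unknown reporter pattern: ", paste(pattern, collapse = ","),
         " (expected one of ", paste(patterns, collapse = ", "), ")")
  if (is.null(noise_sd)) noise_sd <- scene$params$noise_sd
  g <- scene$grid
  H <- scene$H
  ny <- g$ny; nx <- g$nx
  nz <- dim(scene$wall_stack$intensities)[1L]
  xs <- (seq_len(nx) - 1) * g$pixel_xy
  ys <- (seq_len(ny) - 1) * g$pixel_xy
  gx <- matrix(rep(xs, each = ny), ny, nx)
  gy <- matrix(rep(ys, times = nx), ny, nx)
  mask <- switch(pattern,
    none = matrix(FALSE, ny, nx),
    uniform = matrix(TRUE, ny, nx),
    pz_patches = {
      mk <- matrix(FALSE, ny, nx)
      rad <- scene$params$primordium_radius
      for (k in seq_len(nrow(scene$true_incipient)))
        mk <- mk | ((gx - scene$true_incipient$x[k])^2 +
                      (gy - scene$true_incipient$y[k])^2 < rad^2)
      mk
    },
    abaxial_primordia = {
      mk <- matrix(FALSE, ny, nx)
      b <- scene$surface$bumps
      ctr <- scene$surface$center
      for (k in seq_len(nrow(b))) {
        ux <- gx - b$x[k]; uy <- gy - b$y[k]
        outward <- c(b$x[k] - ctr[1L], b$y[k] - ctr[2L])
        outward <- outward / sqrt(sum(outward^2))
        mk <- mk | (ux^2 + uy^2 < (1.5 * b$sp[k])^2 &
                      (ux * outward[1L] + uy * outward[2L]) > 0)
      }
      mk
    })
  nxp <- nx
  Hx <- (H[, c(2:nxp, nxp)] - H[, c(1, 1:(nxp - 1L))]) / (2 * g$pixel_xy)
  Hy <- (H[c(2:ny, ny), ] - H[c(1, 1:(ny - 1L)), ]) / (2 * g$pixel_xy)
  sl <- sqrt(1 + Hx^2 + Hy^2)
  arr <- array(0, c(nz, ny, nx))
  if (pattern != "none") {
    for (i in seq_len(nz)) {
      zi <- g$z_top - (i - 1L) * g$z_step
      dn <- (H - zi) / sl             # depth along the surface normal
      arr[i, , ] <- amplitude * mask * (dn >= band[1L] & dn <= band[2L])
    }
    if (noise_sd > 0)
      arr[] <- with_seed(noise_seed,
                         pmax(0, arr + rnorm(length(arr), 0, noise_sd)))
  }
  out <- volume_stack(arr, voxel_size = c(g$z_step, g$pixel_xy, g$pixel_xy),
                      z_top = g$z_top)
  attr(out, "footprint") <- mask
  out
}

#' Write a synthetic scene to disk
#'
#' Mesh as binary PLY with per-triangle `cell_label`, wall stack (and any
#' reporter stacks) as multi-page TIFF with voxel metadata, ground truth as
#' CSV (`cell_id`, `is_region`, `zone`, `area_um2`) and the generation
#' parameters as a JSON sidecar.
#'
#' @param scene a [generate_apex_scene()] scene.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ply(scene$mesh, file.path(dir, "mesh.ply"),
            face_labels = seg_labels(scene$true_segmentation))
  write_stack_tiff(scene$wall_stack, file.path(dir, "wall.tif"))
  for (nmr in names(scene$reporter_stacks))
    write_stack_tiff(scene$reporter_stacks[[nmr]],
                     file.path(dir, paste0("reporter_", nmr, ".tif")))
  ca <- cell_areas(scene$mesh, scene$true_segmentation)
  ids <- as.integer(names(ca))
  graph <- build_cell_graph(scene$true_segmentation, scene$mesh)
  region <- list(cell_ids = scene$true_region,
                 central_cell = scene$true_central_cell)
  rings <- bfs_rings(graph, scene$true_central_cell,
                     restrict = scene$true_region)
  zone <- rep("outside", length(ids))
  zone[match(names(rings)[rings <= 2], ids)] <- "CZ"
  zone[match(names(rings)[rings >= 3 & rings <= 5], ids)] <- "PZ_ring"
  write.csv(data.frame(cell_id = ids,
                       is_region = ids %in% scene$true_region,
                       zone = zone, area_um2 = as.numeric(ca)),
            file.path(dir, "truth_cells.csv"), row.names = FALSE)
  params <- scene$params
  class(params) <- NULL
  jsonlite::write_json(list(preset = params, seed = scene$seed,
                            grid = scene$grid,
                            package_version =
                              as.character(packageVersion("meristemorph"))),
                       file.path(dir, "params.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

# bilinear lookup of matrix values at fractional (row, col) positions
bilinear_lookup <- function(M, fi, fj) {
  ny <- nrow(M); nx <- ncol(M)
  fi <- pmin(pmax(fi, 1), ny)
  fj <- pmin(pmax(fj, 1), nx)
  i0 <- pmin(floor(fi), ny - 1L); j0 <- pmin(floor(fj), nx - 1L)
  di <- fi - i0; dj <- fj - j0
  M[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    M[cbind(i0 + 1L, j0)] * di * (1 - dj) +
    M[cbind(i0, j0 + 1L)] * (1 - di) * dj +
    M[cbind(i0 + 1L, j0 + 1L)] * di * dj
}
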