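test_that("areas match closed forms and partition the surface", {
  # unit planar square from two triangles
  sq <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
                     rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
  expect_equal(mesh_area(sq), 1.0)
  # icosphere area vs 4 pi r^2
  sp <- sphere25()
  expect_lt(abs(mesh_area(sp) / (4 * pi * 625) - 1), 0.01)
  # segmented mesh: cell areas sum to mesh area
  sc <- small_scene()
  ca <- cell_areas(sc$mesh, sc$true_segmentation)
  expect_lt(abs(sum(ca) / mesh_area(sc$mesh) - 1), 1e-6)
  expect_error(cell_area(sc$mesh, sc$true_segmentation, 999999L),
               "unknown cell_id")
})

test_that("mesh construction validates input", {
  expect_error(surface_mesh(rbind(c(0, 0, NA)), rbind(c(1L, 1L, 1L))),
               "non-finite")
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
                            rbind(c(1L, 2L, 4L))), "out of range")
  # zero-area triangle rejected
  expect_error(surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                            rbind(c(1L, 2L, 3L))), "degenerate")
})

test_that("Gaussian curvature matches closed forms", {
  sp <- sphere25()
  cf <- gaussian_curvature(sp, 10)
  expect_true(all(cf$defined))
  expect_lt(max(abs(cf$K / (1 / 625) - 1)), 0.05)
  # plane: K = 0
  cp <- gaussian_curvature(plane_mesh(), 10)
  expect_lt(max(abs(cp$K), na.rm = TRUE), 1e-4)
  # saddle z = (x^2 - y^2)/(2c): K(0) = -1/c^2
  sm <- saddle_mesh(20)
  cs <- gaussian_curvature(sm, 10)
  ctr <- which(sm$vertices[, 1] == 20 & sm$vertices[, 2] == 20)
  expect_lt(abs(cs$K[ctr] / (-1 / 400) - 1), 0.10)
})

test_that("curvature sign agrees with the angle-defect oracle", {
  bm <- bump_mesh()
  cf <- gaussian_curvature(bm, 10)
  ad <- angle_defect_curvature(bm)
  ok <- cf$defined & !is.na(ad)
  # restrict to vertices clearly above the noise floor of either estimator
  floor_K <- 0.1 * max(abs(cf$K[ok]))
  strong <- ok & abs(cf$K) > floor_K & abs(ad) > 0
  agree <- sign(cf$K[strong]) == sign(ad[strong])
  expect_gte(mean(agree), 0.95)
})

test_that("curvature field flags sparse neighborhoods instead of zeroing", {
  # a coarse mesh with a radius that leaves boundary vertices data-starved
  sq <- plane_mesh(extent = 8, d = 2)
  cf <- gaussian_curvature(sq, radius = 4.5, min_neighbors = 6L)
  expect_true(is.na(cf$K[1]) || cf$n_neighbors[1] >= 6)
  expect_identical(cf$defined, !is.na(cf$K))
  # radius must exceed twice the median edge
  expect_error(gaussian_curvature(sq, radius = 2), "median edge")
})

test_that("curvature is invariant under rigid motion and scales as 1/s^2", {
  bm <- bump_mesh()
  cf <- gaussian_curvature(bm, 10)
  # rigid rotation + translation
  th <- 0.71
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  R2 <- rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  Vr <- sweep(bm$vertices %*% t(R2 %*% R), 2, c(5, -3, 11), "+")
  bmr <- surface_mesh(Vr, bm$triangles)
  cfr <- gaussian_curvature(bmr, 10)
  sel <- cf$defined & cfr$defined & abs(cf$K) > 1e-8
  expect_lt(max(abs(cfr$K[sel] - cf$K[sel]) / abs(cf$K[sel])), 1e-6)
  # uniform scale s: K -> K / s^2 (radius scales with the mesh)
  s <- 2.5
  bms <- surface_mesh(bm$vertices * s, bm$triangles)
  cfs <- gaussian_curvature(bms, 10 * s)
  expect_lt(max(abs(cfs$K[sel] * s^2 - cf$K[sel]) / abs(cf$K[sel])), 0.01)
})

test_that("curvilinear distance matches planar and great-circle lengths", {
  pm <- plane_mesh()
  expect_equal(as.numeric(curvilinear_distance(pm, c(3, 5, 0), c(3, 5, 0))), 0)
  d <- as.numeric(curvilinear_distance(pm, c(3.2, 5.1, 0), c(31.7, 27.3, 0)))
  expect_lt(abs(d / sqrt(28.5^2 + 22.2^2) - 1), 0.01)
  # sphere r = 30, polar angle 60 degrees: arc = r * pi/3
  sp <- sphere30()
  a <- c(0, 0, 30)
  b <- c(30 * sin(pi / 3), 0, 30 * cos(pi / 3))
  arc <- as.numeric(curvilinear_distance(sp, a, b))
  expect_lt(abs(arc / (10 * pi) - 1), 0.02)
  expect_gte(arc, sqrt(sum((a - b)^2)))
})

test_that("curvilinear distance is symmetric and satisfies the triangle
           inequality on sampled triples", {
  sp <- sphere30()
  set.seed(42)
  pts <- lapply(1:4, function(i) {
    u <- rnorm(3); 30 * u / sqrt(sum(u^2))
  })
  dd <- function(p, q) as.numeric(curvilinear_distance(sp, p, q))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(dd(pts[[i]], pts[[j]]) - dd(pts[[j]], pts[[i]])), 1e-9)
  }
  for (tri in list(c(1, 2, 3), c(1, 3, 4), c(2, 3, 4))) {
    d13 <- dd(pts[[tri[1]]], pts[[tri[3]]])
    expect_lte(d13, (dd(pts[[tri[1]]], pts[[tri[2]]]) +
                       dd(pts[[tri[2]]], pts[[tri[3]]])) * 1.01)
  }
  # via constraint: path through a waypoint is never shorter
  d_direct <- dd(pts[[1]], pts[[2]])
  d_via <- as.numeric(curvilinear_distance(sp, pts[[1]], pts[[2]],
                                           via = pts[[3]]))
  expect_gte(d_via, d_direct - 1e-9)
})

test_that("PLY and OBJ round-trips preserve geometry and labels", {
  sc <- small_scene()
  lab <- seg_labels(sc$true_segmentation)
  f_bin <- tempfile(fileext = ".ply")
  f_asc <- tempfile(fileext = ".ply")
  f_obj <- tempfile(fileext = ".obj")
  write_ply(sc$mesh, f_bin, face_labels = lab,
            vertex_props = list(gaussian_curvature = seq_len(
              nrow(sc$mesh$vertices)) * 0.001))
  write_ply(sc$mesh, f_asc, face_labels = lab, binary = FALSE)
  write_obj(sc$mesh, f_obj)
  m_bin <- read_ply(f_bin)
  m_asc <- read_ply(f_asc)
  m_obj <- read_obj(f_obj)
  expect_lt(max(abs(m_bin$vertices - sc$mesh$vertices)), 1e-3)
  expect_identical(m_bin$triangles, sc$mesh$triangles)
  expect_identical(attr(m_bin, "face_props")$cell_label, lab)
  expect_equal(attr(m_bin, "vertex_props")$gaussian_curvature[10], 0.010,
               tolerance = 1e-6)
  expect_lt(max(abs(m_asc$vertices - sc$mesh$vertices)), 1e-5)
  expect_identical(as.integer(attr(m_asc, "face_props")$cell_label), lab)
  expect_equal(m_obj$vertices, sc$mesh$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
})
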