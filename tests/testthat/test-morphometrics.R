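test_that("the summit cell is found, translation-invariant and has a
           deterministic tie-break", {
  an <- small_analysis()
  expect_identical(an$central, an$scene$true_central_cell)
  # translation cannot change the cell
  m2 <- surface_mesh(sweep(an$scene$mesh$vertices, 2, c(13, -7, 4), "+"),
                     an$scene$mesh$triangles)
  expect_identical(find_central_cell(m2, an$scene$true_segmentation),
                   an$central)
  # two equal-height summit vertices: lowest vertex index decides
  V <- rbind(c(0, 0, 1), c(2, 0, 1), c(1, 1, 0), c(1, -1, 0))
  F <- rbind(c(1L, 4L, 3L), c(2L, 3L, 4L))
  m3 <- surface_mesh(V, F)
  seg3 <- cell_segmentation(c(1L, 2L))
  expect_identical(find_central_cell(m3, seg3), 1L)
})

test_that("meristem delimitation recovers the ground-truth region", {
  an <- small_analysis()
  sc <- an$scene
  truth_mask <- seg_labels(sc$true_segmentation) %in% sc$true_region
  det_mask <- seg_labels(sc$true_segmentation) %in% an$region$cell_ids
  expect_gte(area_jaccard(sc$mesh, truth_mask, det_mask), 0.90)
  ca <- cell_areas(sc$mesh, sc$true_segmentation)
  truth_area <- sum(ca[as.character(sc$true_region)])
  expect_gte(an$region$area / truth_area, 0.9)
  expect_lte(an$region$area / truth_area, 1.1)
  # boundary cells are outside the region and the region holds the summit
  expect_length(intersect(an$region$boundary_cells, an$region$cell_ids), 0)
  expect_true(an$central %in% an$region$cell_ids)
  expect_equal(an$region$area,
               sum(ca[as.character(an$region$cell_ids)]))
})

test_that("a pure spherical cap yields the whole surface with empty
           boundary", {
  sp <- icosphere(20, 3)
  keep <- sp$vertices[, 3] > 6
  vid <- which(keep)
  F <- sp$triangles
  fin <- F[rowSums(matrix(F %in% vid, nrow(F))) == 3, , drop = FALSE]
  remap <- match(seq_len(nrow(sp$vertices)), vid)
  cap <- surface_mesh(sp$vertices[vid, ], matrix(remap[fin], ncol = 3))
  # ~25 synthetic cells by nearest-seed labeling
  set.seed(3)
  seeds <- cap$vertices[sample(nrow(cap$vertices), 25), ]
  tc <- (cap$vertices[cap$triangles[, 1], ] +
           cap$vertices[cap$triangles[, 2], ] +
           cap$vertices[cap$triangles[, 3], ]) / 3
  lab <- apply(tc, 1, function(p)
    which.min(colSums((t(seeds) - p)^2)))
  segm <- cell_segmentation(as.integer(lab))
  graph <- build_cell_graph(segm, cap)
  curv <- gaussian_curvature(cap, 8)
  central <- find_central_cell(cap, segm)
  region <- delimit_meristem(cap, segm, curv, graph, central)
  expect_setequal(region$cell_ids, graph$nodes)
  expect_length(region$boundary_cells, 0)
})

test_that("delimitation errors when the central cell sits in a saddle", {
  sm <- saddle_mesh(10, extent = 15, d = 0.75)
  lab <- rep(1L, nrow(sm$triangles))
  lab[seq(1, length(lab), by = 2)] <- 2L   # two interleaved labels suffice
  # label by quadrant instead for a valid patchy segmentation
  tc <- (sm$vertices[sm$triangles[, 1], ] + sm$vertices[sm$triangles[, 2], ] +
           sm$vertices[sm$triangles[, 3], ]) / 3
  lab <- 1L + (tc[, 1] > 15) + 2L * (tc[, 2] > 15)
  segm <- cell_segmentation(as.integer(lab))
  graph <- build_cell_graph(segm, sm)
  curv <- gaussian_curvature(sm, 8)
  # cells around the saddle origin have negative mean curvature
  cellK <- meristemorph:::cell_mean_curvature(sm, segm, curv)
  neg <- as.integer(names(cellK)[which.min(cellK)])
  expect_error(delimit_meristem(sm, segm, curv, graph, neg),
               "no meristem found")
})

test_that("zonation rings equal brute-force BFS and behave monotonically", {
  an <- small_analysis()
  rings <- bfs_rings(an$graph, an$central, restrict = an$region$cell_ids)
  oracle <- oracle_bfs(an$graph, an$central, restrict = an$region$cell_ids)
  expect_identical(rings[order(as.integer(names(rings)))],
                   oracle[order(as.integer(names(oracle)))])
  z <- an$zones
  expect_identical(z$ring[z$cell_id == an$central], 0L)
  expect_identical(z$zone[z$cell_id == an$central], "CZ")
  # ring difference between adjacent region cells is at most 1
  for (v in z$cell_id) {
    nb <- intersect(an$graph$adjacency[[as.character(v)]], z$cell_id)
    if (!length(nb)) next
    expect_lte(max(abs(z$ring[match(nb, z$cell_id)] -
                         z$ring[z$cell_id == v])), 1L)
  }
  # enlarging cz_max never shrinks the CZ
  cz2 <- assign_zones(an$graph, an$region, cz_max = 2L)
  cz3 <- assign_zones(an$graph, an$region, cz_max = 3L)
  expect_true(all(cz2$cell_id[cz2$zone == "CZ"] %in%
                    cz3$cell_id[cz3$zone == "CZ"]))
})

test_that("hexagonal ring k holds exactly 6k cells", {
  hx <- hex_fixture()
  graph <- build_cell_graph(hx$segmentation, hx$mesh)
  rings <- bfs_rings(graph, hx$central)
  for (k in 1:3)
    expect_identical(sum(rings == k), 6L * k)
})

test_that("apex summaries are internally consistent", {
  an <- small_analysis()
  rec <- summarize_apex(an$scene$mesh, an$scene$true_segmentation,
                        an$region, an$zones, apex_id = "t", genotype = "WT",
                        condition = "veg")
  expect_identical(rec$cell_number, length(an$region$cell_ids))
  expect_equal(rec$median_cell_area, median(rec$cell_areas))
  expect_equal(rec$meristem_area, sum(rec$cell_areas))
  expect_true(all(c("CZ", "PZ_ring") %in% rec$zone_summary$zone))
  # zone medians recomputable from the cell list
  cz_ids <- an$zones$cell_id[an$zones$zone == "CZ"]
  expect_equal(rec$zone_summary$median[rec$zone_summary$zone == "CZ"],
               median(rec$cell_areas[as.character(cz_ids)]))
})

test_that("per-zone medians track a uniform tessellation's cell area", {
  sc <- small_scene_uniform()
  a_nom <- sc$params$median_cell_area
  graph <- build_cell_graph(sc$true_segmentation, sc$mesh)
  curv <- gaussian_curvature(sc$mesh, 10)
  central <- find_central_cell(sc$mesh, sc$true_segmentation)
  region <- delimit_meristem(sc$mesh, sc$true_segmentation, curv, graph,
                             central)
  zones <- assign_zones(graph, region)
  rec <- summarize_apex(sc$mesh, sc$true_segmentation, region, zones)
  for (z in c("CZ", "PZ_ring")) {
    med <- rec$zone_summary$median[rec$zone_summary$zone == z]
    expect_lt(abs(med / a_nom - 1), 0.10)
  }
})

test_that("primordia are located at the generator's bumps", {
  an <- small_analysis()
  sc <- an$scene
  prim <- locate_primordia(sc$mesh, sc$true_segmentation, an$curvature,
                           an$region)
  expect_identical(nrow(prim), nrow(sc$true_primordia))
  # match by age rank (youngest = smallest bump): centroid within 5 um
  for (k in seq_len(nrow(prim))) {
    dx <- prim$x[k] - sc$true_primordia$x[k]
    dy <- prim$y[k] - sc$true_primordia$y[k]
    expect_lt(sqrt(dx^2 + dy^2), 5)
  }
  # successive azimuths differ by the divergence angle (mod 360) +- 10 deg
  div <- sc$params$divergence_angle
  for (k in 2:nrow(prim)) {
    delta <- (prim$azimuth[k - 1] - prim$azimuth[k]) %% 360
    expect_lt(min(abs(delta - div), abs(delta - (360 - div))), 10)
  }
})

test_that("a scene without bumps yields no primordia", {
  p <- small_uniform_preset(n_primordia = 0L)
  sc <- generate_apex_scene(p, seed = 4)
  graph <- build_cell_graph(sc$true_segmentation, sc$mesh)
  curv <- gaussian_curvature(sc$mesh, 10)
  central <- find_central_cell(sc$mesh, sc$true_segmentation)
  region <- delimit_meristem(sc$mesh, sc$true_segmentation, curv, graph,
                             central)
  prim <- locate_primordia(sc$mesh, sc$true_segmentation, curv, region)
  expect_identical(nrow(prim), 0L)
})

test_that("incipient positions extrapolate by the divergence angle", {
  base <- data.frame(id = "P1", age_rank = 1L, x = 10, y = 0, z = 1,
                     azimuth = 0, area = 50, n_cells = 3L)
  pred <- predict_incipient_positions(base, divergence = 137.5, k = 2L)
  expect_equal(pred$azimuth, c(137.5, 275.0))
  expect_error(predict_incipient_positions(base[0, ]), "primordium")
  # on a full scene the prediction lands near the generator's next position
  an <- small_analysis()
  sc <- an$scene
  prim <- locate_primordia(sc$mesh, sc$true_segmentation, an$curvature,
                           an$region)
  pred <- predict_incipient_positions(prim, k = 1L, region = an$region,
                                      mesh = sc$mesh,
                                      segmentation = sc$true_segmentation)
  err <- abs(((pred$azimuth[1] - sc$true_incipient$azimuth[1]) + 180) %%
               360 - 180)
  expect_lt(err, 15)
})

test_that("region area is stable under curvature noise and covariant
           under scaling", {
  an <- small_analysis()
  sc <- an$scene
  # noise: uniform perturbation at 5% of the K dynamic range
  K <- an$curvature$K
  rng <- diff(range(K, na.rm = TRUE))
  set.seed(99)
  amp <- 0.05 * rng * sqrt(3)        # uniform noise with sd = 5% of range
  noisy <- an$curvature
  noisy$K <- K + runif(length(K), -amp, amp)
  reg2 <- delimit_meristem(sc$mesh, sc$true_segmentation, noisy, an$graph,
                           an$central)
  expect_lt(abs(reg2$area / an$region$area - 1), 0.05)
  # scale covariance: s^2 area, same cell count
  s <- 1.7
  ms <- surface_mesh(sc$mesh$vertices * s, sc$mesh$triangles)
  curvs <- gaussian_curvature(ms, 10 * s)
  regs <- delimit_meristem(ms, sc$true_segmentation, curvs, an$graph,
                           an$central)
  expect_lt(abs(regs$area / (s^2 * an$region$area) - 1), 0.01)
  expect_identical(regs$cell_count, an$region$cell_count)
})
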