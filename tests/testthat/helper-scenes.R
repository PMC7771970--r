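# Shared synthetic scenes, built once per test run (generation is the
# expensive step). Small presets keep unit-test scenes fast; acceptance
# checks use the full named presets.

small_skewed_preset <- function(...) {
  # miniature apex with the vegetative-style skewed cell-size distribution
  args <- modifyList(list(meristem_cap_area = 1200, n_cells = 96L,
                          median_cell_area = (4 / (3.5 * 1.8)) * 1200 / 96,
                          dome_height = 6, primordium_radius = 4,
                          primordium_height = 2.5),
                     list(...))
  do.call(apex_preset, c(list(name = "vegetative"), args))
}

small_uniform_preset <- function(...) {
  args <- modifyList(list(meristem_cap_area = 1100, n_cells = 64L,
                          median_cell_area = 1100 / 64, dome_height = 9,
                          primordium_radius = 4, primordium_height = 2.5),
                     list(...))
  do.call(apex_preset, c(list(name = "domed"), args))
}

small_scene <- function() cached("small_scene", function()
  generate_apex_scene(small_skewed_preset(), seed = 11))

small_scene_uniform <- function() cached("small_scene_uniform", function()
  generate_apex_scene(small_uniform_preset(), seed = 12))

small_scene_clean <- function() cached("small_scene_clean", function()
  generate_apex_scene(small_skewed_preset(noise_sd = 0), seed = 11))

small_scene_uniform_clean <- function() cached("small_scene_uniform_clean",
  function() generate_apex_scene(small_uniform_preset(noise_sd = 0),
                                 seed = 12))

# extraction + wall projection for the clean uniform scene, shared by the
# watershed tests
uniform_clean_extraction <- function() cached("uniform_clean_extraction",
  function() {
    sc <- small_scene_uniform_clean()
    mesh <- extract_surface(sc$wall_stack,
                            0.25 * max(sc$wall_stack$intensities))
    list(mesh = mesh, wall = project_wall_signal(sc$wall_stack, mesh))
  })

# truth-cell labels whose triangles touch the rectangular field border
border_cells <- function(scene) {
  V <- scene$mesh$vertices
  xr <- range(V[, 1]); yr <- range(V[, 2])
  on_rim <- V[, 1] %in% xr | V[, 2] %in% yr
  F <- scene$mesh$triangles
  touches <- on_rim[F[, 1]] | on_rim[F[, 2]] | on_rim[F[, 3]]
  unique(seg_labels(scene$true_segmentation)[touches])
}

# truth-side analysis bundle for the small scene (graph, curvature, region)
small_analysis <- function() cached("small_analysis", function() {
  sc <- small_scene()
  graph <- build_cell_graph(sc$true_segmentation, sc$mesh)
  curv <- gaussian_curvature(sc$mesh, 10)
  central <- find_central_cell(sc$mesh, sc$true_segmentation)
  region <- delimit_meristem(sc$mesh, sc$true_segmentation, curv, graph,
                             central)
  zones <- assign_zones(graph, region)
  list(scene = sc, graph = graph, curvature = curv, central = central,
       region = region, zones = zones)
})
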