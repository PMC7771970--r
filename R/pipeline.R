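#' Quantify one apex from a wall-stain stack
#'
#' The core 2.5D chain for one apex: surface extraction, wall-signal
#' projection, (seeded or automatic) watershed segmentation, Gaussian
#' curvature at the configured neighborhood radius, summit cell,
#' curvature-based meristem delimitation, zonation and the morphometric
#' record.
#'
#' @param stack wall-stain [volume_stack()].
#' @param threshold surface-extraction intensity threshold; `NULL` picks
#'   25% of the stack maximum.
#' @param smooth_sigma height-map smoothing (µm) passed to
#'   [extract_surface()].
#' @param wall_band depth band (µm) for wall-signal projection.
#' @param curvature_radius neighborhood radius (µm) for Gaussian curvature.
#' @param seeds optional watershed seed points (k x 3).
#' @param min_cell_area watershed sliver-merge threshold (µm²).
#' @param include_boundary count saddle cells in the region.
#' @param cz_max,pz_max zonation ring limits.
#' @param apex_id,genotype,condition labels for the record.
#' @return list with `mesh`, `wall_signal`, `segmentation`, `graph`,
#'   `curvature`, `central_cell`, `region`, `zones`, `record`.
#' @export
quantify_apex <- function(stack, threshold = NULL, smooth_sigma = 2,
                          wall_band = c(0, 4),
                          curvature_radius = 10, seeds = NULL,
                          min_cell_area = 4, include_boundary = FALSE,
                          cz_max = 2L, pz_max = 5L, apex_id = "apex",
                          genotype = "WT", condition = "NA") {
  if (is.null(threshold)) threshold <- 0.25 * max(stack$intensities)
  mesh <- extract_surface(stack, threshold, smooth_sigma = smooth_sigma)
  wall <- project_wall_signal(stack, mesh, band = wall_band)
  segm <- segment_cells(mesh, wall, seeds = seeds,
                        min_cell_area = min_cell_area)
  graph <- build_cell_graph(segm, mesh)
  curv <- gaussian_curvature(mesh, radius = curvature_radius)
  central <- find_central_cell(mesh, segm)
  region <- delimit_meristem(mesh, segm, curv, graph, central,
                             include_boundary = include_boundary)
  zones <- assign_zones(graph, region, cz_max = cz_max, pz_max = pz_max)
  record <- summarize_apex(mesh, segm, region, zones, apex_id = apex_id,
                           genotype = genotype, condition = condition)
  list(mesh = mesh, wall_signal = wall, segmentation = segm, graph = graph,
       curvature = curv, central_cell = central, region = region,
       zones = zones, record = record)
}

#' Run the full synthetic-apex analysis pipeline from a config
#'
#' Executes generate -> extract -> segment -> curvature -> delimit ->
#' zonate -> summarize (-> signal projection) for every (preset, seed)
#' apex in the plan, then group statistics (ANOVA + Tukey + letters) and
#' fold changes against the configured baseline. Writes per-apex cell
#' CSVs, a summary CSV, comparison tables, optional heat maps and a run
#' log with the fully resolved configuration, seeds and package version.
#'
#' @param config a named list, or the path to a YAML file, with entries:
#'   `output_dir` (required); `plan`: list of groups, each with `preset`,
#'   `seeds` (vector), optional `genotype`, `condition`, `overrides`
#'   (preset field overrides); optional `params`: `threshold`,
#'   `wall_band`, `curvature_radius`, `min_cell_area`, `cz_max`, `pz_max`,
#'   `pixel_xy`, `z_step`; optional `reporters`: patterns to render and
#'   project per apex; optional `stats`: `baseline`, `alpha`,
#'   `measures`; optional `heatmaps` (logical).
#' @return invisibly, list with `summary` (data.frame), `comparisons`
#'   (list of [anova_tukey()] results per measure), `fold_changes`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$output_dir))
    stop("config validation: 'output_dir' is required")
  if (is.null(config$plan) || !length(config$plan))
    stop("config validation: 'plan' with at least one group is required")
  for (g in config$plan) {
    if (is.null(g$preset)) stop("config validation: plan entry lacks 'preset'")
    if (is.null(g$seeds)) stop("config validation: plan entry lacks 'seeds'")
  }
  prm <- modifyList(list(threshold = NULL, smooth_sigma = 2,
                         wall_band = c(0, 4),
                         curvature_radius = 10, min_cell_area = 4,
                         cz_max = 2L, pz_max = 5L, pixel_xy = 0.5,
                         z_step = 0.4),
                    if (is.null(config$params)) list() else config$params)
  st <- modifyList(list(baseline = NULL, alpha = 0.05,
                        measures = c("meristem_area", "cell_number",
                                     "median_cell_area")),
                   if (is.null(config$stats)) list() else config$stats)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$output_dir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(...))
    cat(line, "\n", file = logfile, append = TRUE, sep = "")
    message(line)
  }
  logmsg("meristemorph %s pipeline start",
         as.character(packageVersion("meristemorph")))
  cat(yaml::as.yaml(list(resolved_config = c(config, list(params = prm,
                                                          stats = st)))),
      file = logfile, append = TRUE)
  rows <- list()
  for (g in config$plan) {
    preset <- do.call(apex_preset,
                      c(list(name = g$preset),
                        if (is.null(g$overrides)) list() else g$overrides))
    genotype <- if (is.null(g$genotype)) "WT" else g$genotype
    condition <- if (is.null(g$condition)) g$preset else g$condition
    for (sd in g$seeds) {
      apex_id <- sprintf("%s_s%d", condition, sd)
      stage <- "generate"
      res <- tryCatch({
        scene <- generate_apex_scene(preset, seed = sd,
                                     pixel_xy = prm$pixel_xy,
                                     z_step = prm$z_step)
        stage <- "quantify"
        q <- quantify_apex(scene$wall_stack, threshold = prm$threshold,
                           smooth_sigma = prm$smooth_sigma,
                           wall_band = prm$wall_band,
                           curvature_radius = prm$curvature_radius,
                           min_cell_area = prm$min_cell_area,
                           cz_max = prm$cz_max, pz_max = prm$pz_max,
                           apex_id = apex_id, genotype = genotype,
                           condition = condition)
        stage <- "report"
        write_morphometrics(q$mesh, q$segmentation, q$region, q$zones,
                            q$record,
                            cells_csv = file.path(config$output_dir,
                                                  paste0(apex_id, "_cells.csv")))
        for (rep_pat in config$reporters) {
          stk <- make_reporter_field(scene, rep_pat)
          sm <- project_signal(stk, q$mesh, q$segmentation,
                               reporter = rep_pat)
          write_signal_map(sm, file.path(config$output_dir,
                                         paste0(apex_id, "_", rep_pat,
                                                ".csv")))
          if (isTRUE(config$heatmaps))
            render_heatmap(sm, q$mesh, q$segmentation,
                           file.path(config$output_dir,
                                     paste0(apex_id, "_", rep_pat, ".png")))
        }
        if (isTRUE(config$heatmaps)) {
          ca <- cell_areas(q$mesh, q$segmentation)
          render_heatmap(ca, q$mesh, q$segmentation,
                         file.path(config$output_dir,
                                   paste0(apex_id, "_cell_area.png")))
        }
        q$record
      }, error = function(e) {
        logmsg("FAILED at stage '%s' for apex '%s': %s", stage, apex_id,
               conditionMessage(e))
        stop(sprintf("pipeline stage '%s' failed for apex '%s': %s", stage,
                     apex_id, conditionMessage(e)), call. = FALSE)
      })
      logmsg("apex %s: area %.0f um^2, %d cells, median cell area %.2f",
             apex_id, res$meristem_area, res$cell_number,
             res$median_cell_area)
      rows[[apex_id]] <- res
    }
  }
  summary_df <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(summary_df) <- NULL
  write.csv(summary_df, file.path(config$output_dir, "summary.csv"),
            row.names = FALSE)
  comparisons <- list()
  if (length(unique(summary_df$condition)) >= 2L &&
      min(table(summary_df$condition)) >= 2L) {
    for (ms in st$measures) {
      cmp <- anova_tukey(data.frame(value = summary_df[[ms]],
                                    group = summary_df$condition),
                         alpha = st$alpha)
      comparisons[[ms]] <- cmp
      write.csv(cbind(measure = ms, cmp$tukey),
                file.path(config$output_dir, paste0("tukey_", ms, ".csv")),
                row.names = FALSE)
      write.csv(data.frame(group = names(cmp$letters),
                           letters = unname(cmp$letters)),
                file.path(config$output_dir, paste0("letters_", ms, ".csv")),
                row.names = FALSE)
    }
  }
  fc <- NULL
  if (!is.null(st$baseline)) {
    fc <- fold_changes(summary_df, st$baseline)
    write.csv(fc, file.path(config$output_dir, "fold_changes.csv"),
              row.names = FALSE)
  }
  logmsg("pipeline done: %d apices", nrow(summary_df))
  invisible(list(summary = summary_df, comparisons = comparisons,
                 fold_changes = fc, output_dir = config$output_dir))
}
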