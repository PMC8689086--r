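#' Configuration of an in-silico structured-environment experiment
#'
#' Bundles everything needed to run one of the three experiment kinds end
#' to end: the geometry specification, physical parameters, exposure
#' preset, analysis options and the master seed from which every stage
#' derives its own seed (see [stage_seed()]).
#'
#' @param kind `"micromodel"`, `"trap_chamber"` or `"mock_array"`.
#' @param geometry named list of arguments for the kind's generator
#'   (defaults are the study-scale geometries; see
#'   [generate_micromodel()], [generate_trap_chamber()],
#'   [generate_mock_array()]).
#' @param params a [physical_params()] object.
#' @param preset an [exposure_preset()] or built-in preset name.
#' @param analysis list: `bin_width` (um^2), `nbhd_radius_um`, `n_cells`
#'   (micromodel), `conc` (uM), `solve_flow` (force the flow stage even for
#'   presets that do not need it).
#' @param seed master seed.
#' @param out_dir optional output directory for [run_experiment()].
#' @return an object of class `strucell_config`.
#' @export
experiment_config <- function(kind = c("micromodel", "trap_chamber",
                                       "mock_array"),
                              geometry = list(), params = physical_params(),
                              preset = "micromodel_uncoupled",
                              analysis = list(), seed = 1, out_dir = NULL) {
  kind <- match.arg(kind)
  if (is.character(preset)) preset <- preset(preset)
  def_analysis <- list(bin_width = 1000, nbhd_radius_um = 7, n_cells = 100,
                       conc = 200, solve_flow = FALSE)
  structure(list(kind = kind, geometry = geometry, params = params,
                 preset = preset,
                 analysis = modifyList(def_analysis, analysis),
                 seed = seed, out_dir = out_dir),
            class = "strucell_config")
}

#' Run a structured-environment experiment end to end
#'
#' Executes the stages of the configured experiment in order — geometry
#' generation, cell placement, flow solution (only when the preset or the
#' analysis options require it), spatial metrics, response simulation and
#' summary statistics — and returns everything as a result bundle. Each
#' stage draws its seed deterministically from the master seed, so an
#' identical configuration reproduces identical outputs. When
#' `config$out_dir` is set the bundle is also written to disk (CSV tables,
#' JSON statistics, scene and flow images, plain-text log).
#'
#' @param config an [experiment_config()].
#' @return an object of class `strucell_bundle`: `config`, `scenes`,
#'   `metrics`, `responses`, `stats`, `flow` (optional), `log`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "strucell_config"))
  t0 <- Sys.time()
  log <- c(sprintf("strucell %s experiment, master seed %d",
                   config$kind, config$seed),
           sprintf("preset: %s (%s)", config$preset$name, config$preset$mode))
  bundle <- switch(config$kind,
    micromodel = run_micromodel(config),
    trap_chamber = run_trap_chamber(config),
    mock_array = run_mock_array(config))
  bundle$config <- config
  bundle$log <- c(log, bundle$log,
                  sprintf("completed in %.1f s",
                          as.numeric(Sys.time() - t0, units = "secs")))
  class(bundle) <- "strucell_bundle"
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

run_micromodel <- function(config) {
  an <- config$analysis
  scene <- do.call(generate_micromodel,
                   c(config$geometry,
                     list(seed = stage_seed(config$seed, "geometry"))))
  scene <- place_cells(scene, an$n_cells,
                       seed = stage_seed(config$seed, "placement"))
  metrics <- spatial_metrics(scene)
  log <- sprintf("geometry: %d x %d px, porosity %.3f, %d cells",
                 nrow(scene$mask), ncol(scene$mask), open_fraction(scene),
                 nrow(scene$cells))
  flow <- NULL
  cells_tab <- data.frame(cell_id = metrics$cell_id,
                          area_um2 = metrics$area_um2)
  if (config$preset$mode == "flow_coupled" || isTRUE(an$solve_flow)) {
    flow <- solve_flow(scene, config$params)
    cells_tab$nbhd_speed <- vapply(seq_len(nrow(scene$cells)), function(k)
      neighbourhood_mean_speed(flow, scene$cells[k, ], an$nbhd_radius_um),
      numeric(1))
    log <- c(log, sprintf("flow: %d cycles, continuity residual %.2e",
                          flow$diagnostics$cycles, flow$diagnostics$res_cont))
  }
  responses <- simulate_structured(cells_tab, config$preset, conc = an$conc,
                                   seed = stage_seed(config$seed, "simulate"))
  responses <- merge(responses,
                     metrics[, setdiff(names(metrics), "area_um2")],
                     by = "cell_id")
  pct <- responses$percent_increase
  stats <- list(
    n = nrow(responses),
    cv_percent = cv_percent(pct),
    cor_area = unclass(pearson(responses$area_um2, pct)),
    cor_mean_grey = unclass(pearson(responses$mean_grey, pct)),
    cor_median_grey = unclass(pearson(responses$median_grey, pct)))
  if (!is.null(cells_tab$nbhd_speed))
    stats$cor_nbhd_speed <- unclass(pearson(responses$nbhd_speed, pct))
  list(scenes = list(scene), flow = flow, metrics = metrics,
       responses = responses, stats = stats, log = log)
}

run_trap_chamber <- function(config) {
  an <- config$analysis
  g <- modifyList(list(sphere_means = c(0, 16, 39), sphere_sds = c(0, 5, 8),
                       n_traps = c(59, 58, 62)), config$geometry)
  extra <- g[setdiff(names(g), c("sphere_means", "sphere_sds", "n_traps"))]
  conds <- seq_along(g$sphere_means)
  all_scenes <- list()
  cells_tab <- NULL
  for (ci in conds) {
    traps <- do.call(generate_trap_chamber, c(
      list(n_traps = g$n_traps[ci], mean_spheres = g$sphere_means[ci],
           sd_spheres = g$sphere_sds[ci],
           seed = stage_seed(config$seed, paste0("geometry", ci))), extra))
    areas <- vapply(traps, function(s) spatial_metrics(s)$area_um2[1],
                    numeric(1))
    cells_tab <- rbind(cells_tab, data.frame(
      cell_id = length(all_scenes) + seq_along(traps),
      condition = g$sphere_means[ci], area_um2 = areas,
      n_spheres = vapply(traps, function(s) s$meta$n_spheres, integer(1))))
    all_scenes <- c(all_scenes, traps)
  }
  responses <- simulate_structured(
    cells_tab[, c("cell_id", "area_um2")], config$preset, conc = an$conc,
    seed = stage_seed(config$seed, "simulate"))
  responses$condition <- cells_tab$condition
  responses$n_spheres <- cells_tab$n_spheres
  by_cond <- lapply(split(responses, responses$condition), function(d)
    data.frame(condition = d$condition[1], n = nrow(d),
               mean_area_um2 = mean(d$area_um2),
               mean_pct = mean(d$percent_increase),
               sd_pct = sd(d$percent_increase),
               cv_percent = cv_percent(d$percent_increase)))
  cond_tab <- do.call(rbind, by_cond)
  ref <- cond_tab[cond_tab$condition == min(cond_tab$condition), ]
  cond_tab$area_fold_reduction <- ref$mean_area_um2 / cond_tab$mean_area_um2
  cond_tab$suppression_pct <- 100 * (1 - cond_tab$mean_pct / ref$mean_pct)
  stats <- list(
    conditions = cond_tab,
    pooled_cor = unclass(pearson(responses$area_um2,
                                 responses$percent_increase)),
    binned = bin_by_area(responses$area_um2, responses$percent_increase,
                         an$bin_width))
  list(scenes = all_scenes, metrics = cells_tab, responses = responses,
       stats = stats,
       log = sprintf("trap conditions: %s spheres, n = %s",
                     paste(g$sphere_means, collapse = "/"),
                     paste(g$n_traps, collapse = "/")))
}

run_mock_array <- function(config) {
  g <- modifyList(list(n_objects = 0:8, spacing = c(1, 2)), config$geometry)
  extra <- g[setdiff(names(g), c("n_objects", "spacing"))]
  grid <- expand.grid(n_objects = g$n_objects, spacing = g$spacing)
  scenes <- lapply(seq_len(nrow(grid)), function(k)
    do.call(generate_mock_array,
            c(list(n_objects = grid$n_objects[k], spacing = grid$spacing[k]),
              extra)))
  metrics <- do.call(rbind, lapply(seq_along(scenes), function(k) {
    m <- spatial_metrics(scenes[[k]])
    cbind(grid[k, , drop = FALSE], m[, -1], row.names = NULL)
  }))
  list(scenes = scenes, metrics = metrics, responses = NULL,
       stats = list(configurations = nrow(grid)),
       log = sprintf("%d mock-array configurations", nrow(grid)))
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  if (!is.null(bundle$responses))
    write.csv(bundle$responses, file.path(dir, "responses.csv"),
              row.names = FALSE)
  jsonlite::write_json(bundle$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  writeLines(bundle$log, file.path(dir, "log.txt"))
  save_scene(bundle$scenes[[1]], file.path(dir, "scene1"))
  if (!is.null(bundle$flow))
    export_flow(bundle$flow, file.path(dir, "flow"),
                cells = bundle$scenes[[1]]$cells)
  invisible(dir)
}

#' @export
print.strucell_bundle <- function(x, ...) {
  cat(sprintf("<strucell_bundle> %s experiment, seed %d: %d scene(s)%s\n",
              x$config$kind, x$config$seed, length(x$scenes),
              if (!is.null(x$responses))
                sprintf(", %d cell responses", nrow(x$responses)) else ""))
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}

#' Render figures and a plain-text summary for a result bundle
#'
#' Produces the bundle's report: a flow-speed greyscale render with cells
#' overlaid coloured by their simulated response (when flow was solved), a
#' response-versus-area scatter plot with a least-squares line, the binned
#' response profile (when available), and a plain-text summary whose
#' numbers are exactly the bundle's statistics.
#'
#' @param bundle a [run_experiment()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
render_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "strucell_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scene <- bundle$scenes[[1]]
  # geometry or flow panel with response overlay
  if (!is.null(bundle$flow)) {
    img <- render_speed(bundle$flow)
    overlay_png(img, scene, bundle$responses, file.path(dir, "overlay.png"))
  } else {
    img <- 1 - scene$mask * 1
    overlay_png(img, scene, bundle$responses, file.path(dir, "geometry.png"))
  }
  if (!is.null(bundle$responses) && !is.null(bundle$responses$area_um2)) {
    df <- bundle$responses
    p <- ggplot2::ggplot(df, ggplot2::aes(x = area_um2,
                                          y = percent_increase)) +
      ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                           colour = "firebrick") +
      ggplot2::labs(x = "Voronoi area (um^2)",
                    y = "Fluorescence increase (%)") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "response_vs_area.png"), p,
                    width = 5, height = 4, dpi = 150)
  }
  if (!is.null(bundle$stats$binned)) {
    b <- bundle$stats$binned[bundle$stats$binned$count > 0, ]
    p <- ggplot2::ggplot(b, ggplot2::aes(x = (bin_lo + bin_hi) / 2,
                                         y = mean)) +
      ggplot2::geom_col(fill = "grey70") +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sem,
                                          ymax = mean + sem), width = 300) +
      ggplot2::labs(x = "Voronoi area bin (um^2)",
                    y = "Mean fluorescence increase (%)") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(file.path(dir, "binned_response.png"), p,
                    width = 5, height = 4, dpi = 150)
  }
  writeLines(summary_text(bundle), file.path(dir, "summary.txt"))
  invisible(dir)
}

overlay_png <- function(img, scene, responses, path) {
  rgb_img <- array(rep(img, 3), c(nrow(img), ncol(img), 3))
  if (!is.null(responses) && nrow(scene$cells)) {
    pct <- responses$percent_increase[match(scene$cells$id,
                                            responses$cell_id)]
    rel <- pct / max(pct, na.rm = TRUE)
    for (k in seq_len(nrow(scene$cells))) {
      px <- disc_pixels(scene$cells$row[k], scene$cells$col[k],
                        max(3, scene$cells$diameter_um[k] / 2 /
                              scene$pixel_size),
                        nrow(img), ncol(img))
      rgb_img[cbind(px, 1)] <- rel[k]
      rgb_img[cbind(px, 2)] <- 0.2
      rgb_img[cbind(px, 3)] <- 1 - rel[k]
    }
  }
  png::writePNG(rgb_img, path)
}

summary_text <- function(bundle) {
  s <- bundle$stats
  out <- c(sprintf("experiment: %s", bundle$config$kind),
           sprintf("seed: %d", bundle$config$seed))
  fmt_cor <- function(label, cr)
    sprintf("%s: r = %.6f, R2 = %.6f, p = %.6g, n = %d",
            label, cr$r, cr$r_squared, cr$p_two_sided, cr$n)
  if (!is.null(s$cv_percent))
    out <- c(out, sprintf("population CV = %.6f%%", s$cv_percent))
  for (nm in grep("^cor_|^pooled_cor$", names(s), value = TRUE))
    out <- c(out, fmt_cor(nm, s[[nm]]))
  if (!is.null(s$conditions)) {
    cd <- s$conditions
    out <- c(out, apply(cd, 1, function(r) paste(
      sprintf("condition %s:", r[["condition"]]),
      sprintf("n = %s, mean area = %.6f, mean pct = %.6f, CV = %.6f%%",
              r[["n"]], as.numeric(r[["mean_area_um2"]]),
              as.numeric(r[["mean_pct"]]), as.numeric(r[["cv_percent"]])))))
  }
  out
}
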