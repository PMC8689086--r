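#' Export spatial metrics as images and tables
#'
#' Writes the Voronoi partition of a scene as a labelled TIFF (cell id per
#' pixel), the per-cell metrics table as CSV, and an 8-bit greyscale
#' distance-map render as PNG.
#'
#' @param scene a scene with cells.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
export_metrics <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  regions <- voronoi_partition(scene)
  lab <- voronoi_label_raster(scene, regions)
  tiff::writeTIFF(lab / max(1, max(lab)), file.path(dir, "regions.tiff"),
                  bits.per.sample = 16)
  png::writePNG(grey_render(scene, regions), file.path(dir, "grey_map.png"))
  write.csv(do.call(rbind, lapply(regions, summarize_region,
                                  pixel_size = scene$pixel_size)),
            file.path(dir, "metrics.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read and write exposure presets as YAML
#'
#' @param preset an [exposure_preset()].
#' @param path YAML file path.
#' @return `write_preset_yaml` returns `path` invisibly; `read_preset_yaml`
#'   returns the preset.
#' @export
write_preset_yaml <- function(preset, path) {
  stopifnot(inherits(preset, "strucell_preset"))
  x <- unclass(preset)
  if (!is.null(x$cv_anchors)) x$cv_anchors <- as.list(x$cv_anchors)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_preset_yaml
#' @export
read_preset_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  args <- x[setdiff(names(x), c("name", "mode"))]
  if (!is.null(args$cv_anchors))
    args$cv_anchors <- as.data.frame(args$cv_anchors)
  do.call(exposure_preset, c(list(name = x$name, mode = x$mode), args))
}

#' Read and write experiment configurations as YAML
#'
#' The preset may be given by name (built-ins) or inline as a mapping.
#'
#' @param config an [experiment_config()].
#' @param path YAML file path.
#' @return `read_experiment_config` returns the config.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "strucell_config"))
  x <- list(kind = config$kind, geometry = config$geometry,
            params = unclass(config$params),
            preset = config$preset$name,
            analysis = config$analysis, seed = config$seed,
            out_dir = config$out_dir)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  x <- yaml::read_yaml(path)
  experiment_config(
    kind = x$kind,
    geometry = if (is.null(x$geometry)) list() else x$geometry,
    params = if (is.null(x$params)) physical_params() else
      do.call(physical_params, x$params),
    preset = if (is.null(x$preset)) "micromodel_uncoupled" else x$preset,
    analysis = if (is.null(x$analysis)) list() else x$analysis,
    seed = if (is.null(x$seed)) 1 else x$seed,
    out_dir = x$out_dir)
}
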