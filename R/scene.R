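#' Rasterised structured scene
#'
#' A scene is the package's central geometry container: a binary obstacle
#' raster plus the physical scales and cell positions needed by the flow
#' solver and the spatial metrics. The raster convention is row/column pixel
#' indices (1-based, as usual in R) with pixel centres on the integer grid;
#' areas are open-pixel counts times `pixel_size^2`. Flow always enters at
#' the top edge (row 1) and leaves at the bottom edge.
#'
#' @param mask logical matrix, `TRUE` = solid obstacle.
#' @param pixel_size pixel edge length in micrometres.
#' @param height_um channel (structure) height in micrometres.
#' @param cells data frame with columns `id`, `row`, `col`, `diameter_um`
#'   (may have zero rows).
#' @param roi analysis region `c(row_min, row_max, col_min, col_max)`;
#'   defaults to the full raster.
#' @param meta named list of provenance metadata (generator, seed, ...).
#' @return an object of class `strucell_scene`.
#' @seealso [validate_scene()], [place_cells()], [save_scene()]
#' @export
new_scene <- function(mask, pixel_size, height_um,
                      cells = empty_cells(), roi = NULL, meta = list()) {
  stopifnot(is.matrix(mask), is.logical(mask),
            is.numeric(pixel_size), pixel_size > 0,
            is.numeric(height_um), height_um > 0)
  if (is.null(roi)) roi <- c(1L, nrow(mask), 1L, ncol(mask))
  scene <- structure(
    list(mask = mask, pixel_size = pixel_size, height_um = height_um,
         inlet_edge = "top", outlet_edge = "bottom",
         cells = as.data.frame(cells), roi = as.integer(roi), meta = meta),
    class = "strucell_scene")
  scene
}

empty_cells <- function() {
  data.frame(id = integer(), row = integer(), col = integer(),
             diameter_um = numeric())
}

#' @export
print.strucell_scene <- function(x, ...) {
  cat(sprintf(
    "<strucell_scene> %d x %d px (%.1f x %.1f um at %.2g um/px), h = %g um\n",
    nrow(x$mask), ncol(x$mask), nrow(x$mask) * x$pixel_size,
    ncol(x$mask) * x$pixel_size, x$pixel_size, x$height_um))
  cat(sprintf("  solid fraction %.3f, %d cell(s)%s\n", mean(x$mask),
              nrow(x$cells),
              if (!is.null(x$meta$generator))
                paste0(", generator: ", x$meta$generator) else ""))
  invisible(x)
}

#' Check the invariants of a scene
#'
#' Asserts that the inlet and outlet edges each have at least one open pixel,
#' that an open 4-connected path joins them, that no cell centre lies on a
#' solid pixel or outside the analysis region, that cell ids are unique, and
#' that the physical scales are positive.
#'
#' @param scene a [new_scene()] object.
#' @return the scene, invisibly; stops with an informative error otherwise.
#' @export
validate_scene <- function(scene) {
  stopifnot(inherits(scene, "strucell_scene"))
  m <- scene$mask
  if (scene$pixel_size <= 0) stop("pixel_size must be positive")
  if (scene$height_um <= 0) stop("height_um must be positive")
  open_in <- which(!m[1L, ])
  open_out <- which(!m[nrow(m), ])
  if (length(open_in) == 0L) stop("inlet edge has no open pixel")
  if (length(open_out) == 0L) stop("outlet edge has no open pixel")
  lab <- .label4_cpp(!m)
  if (length(intersect(unique(lab[1L, open_in]),
                       unique(lab[nrow(m), open_out]))) == 0L)
    stop("no open 4-connected path from inlet to outlet")
  cl <- scene$cells
  if (nrow(cl) > 0L) {
    if (anyDuplicated(cl$id)) stop("cell ids are not unique")
    if (any(cl$row < 1L | cl$row > nrow(m) | cl$col < 1L | cl$col > ncol(m)))
      stop("cell centre outside raster")
    if (any(m[cbind(cl$row, cl$col)])) stop("cell centre on a solid pixel")
    r <- scene$roi
    if (any(cl$row < r[1] | cl$row > r[2] | cl$col < r[3] | cl$col > r[4]))
      stop("cell centre outside the analysis region")
  }
  invisible(scene)
}

#' Open-area fraction of a scene
#'
#' @param scene a scene.
#' @param roi_only restrict to the analysis region?
#' @return fraction of pixels that are open (non-solid).
#' @export
open_fraction <- function(scene, roi_only = FALSE) {
  m <- scene$mask
  if (roi_only) {
    r <- scene$roi
    m <- m[r[1]:r[2], r[3]:r[4], drop = FALSE]
  }
  mean(!m)
}

# pixels of a disc of radius `radius_px` centred at (row0, col0), clipped to
# the raster; returns a 2-column matrix of (row, col)
disc_pixels <- function(row0, col0, radius_px, nr, nc) {
  rr <- max(1L, floor(row0 - radius_px)):min(nr, ceiling(row0 + radius_px))
  cc <- max(1L, floor(col0 - radius_px)):min(nc, ceiling(col0 + radius_px))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - row0)^2 + (g$col - col0)^2 <= radius_px^2
  as.matrix(g[keep, , drop = FALSE])
}

# paint solid discs into a logical mask
add_disc <- function(mask, row0, col0, radius_px) {
  px <- disc_pixels(row0, col0, radius_px, nrow(mask), ncol(mask))
  mask[px] <- TRUE
  mask
}

#' Place cells uniformly in the open space of a scene
#'
#' Samples `n` distinct open pixels (uniformly, without replacement) that are
#' inside the analysis region and at least `diameter/2 + min_clearance` away
#' from any solid pixel, and appends them as cells. Placement is
#' deterministic under a fixed seed. Cells are used for placement clearance
#' only; they are never added to the obstacle mask seen by the flow solver.
#'
#' @param scene a scene.
#' @param n number of cells to place.
#' @param min_clearance extra clearance beyond the cell radius, micrometres.
#' @param seed integer seed.
#' @param diameter cell diameter in micrometres (default 4.5, mid-range of
#'   the 4-5 um of budding yeast).
#' @return the scene with `n` additional cells.
#' @export
place_cells <- function(scene, n, min_clearance = 0, seed = NULL,
                        diameter = 4.5) {
  stopifnot(inherits(scene, "strucell_scene"), n >= 0)
  if (n == 0L) return(scene)
  need_px <- (diameter / 2 + min_clearance) / scene$pixel_size
  d2 <- if (any(scene$mask)) .edt_cpp(scene$mask)$dist2 else
    matrix(Inf, nrow(scene$mask), ncol(scene$mask))
  r <- scene$roi
  ok <- !scene$mask & d2 > need_px^2
  # keep the whole cell footprint inside the analysis region
  inset <- ceiling(diameter / 2 / scene$pixel_size)
  sel <- matrix(FALSE, nrow(ok), ncol(ok))
  sel[max(1, r[1] + inset):min(nrow(ok), r[2] - inset),
      max(1, r[3] + inset):min(ncol(ok), r[4] - inset)] <- TRUE
  cand <- which(ok & sel)
  if (length(cand) < n)
    stop(sprintf("placement error: only %d qualifying open pixels for %d cells",
                 length(cand), n))
  pick <- with_seed(seed, sample(cand, n))
  id0 <- if (nrow(scene$cells)) max(scene$cells$id) else 0L
  scene$cells <- rbind(scene$cells, data.frame(
    id = id0 + seq_len(n),
    row = as.integer((pick - 1L) %% nrow(ok) + 1L),
    col = as.integer((pick - 1L) %/% nrow(ok) + 1L),
    diameter_um = diameter))
  scene$meta$cell_seed <- seed
  scene
}

#' Save and load scenes
#'
#' A scene is serialised as an 8-bit greyscale PNG obstacle mask (solid =
#' 255, open = 0) plus a JSON sidecar holding the physical scales, edges,
#' analysis region, cells and metadata, and a `cells.csv` table. The
#' round trip `load_scene(save_scene(s))` reproduces the mask bit-exactly.
#'
#' @param scene a scene.
#' @param dir directory to write into (created if missing).
#' @return `save_scene` returns `dir` invisibly; `load_scene` returns the
#'   scene.
#' @export
save_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png::writePNG(scene$mask * 1, file.path(dir, "mask.png"))
  meta <- list(pixel_size = scene$pixel_size, height_um = scene$height_um,
               inlet_edge = scene$inlet_edge, outlet_edge = scene$outlet_edge,
               roi = scene$roi, cells = scene$cells, meta = scene$meta)
  jsonlite::write_json(meta, file.path(dir, "scene.json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(scene$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_scene
#' @export
load_scene <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "scene.json"),
                              simplifyVector = TRUE)
  scene <- load_mask(file.path(dir, "mask.png"),
                     pixel_size = meta$pixel_size,
                     height_um = meta$height_um)
  cl <- as.data.frame(meta$cells)
  scene$cells <- if (nrow(cl)) cl else empty_cells()
  scene$roi <- as.integer(meta$roi)
  scene$meta <- as.list(meta$meta)
  scene
}

#' Load an obstacle mask image as a scene
#'
#' Reads a single-channel 8-bit PNG and binarises it: a pixel is solid
#' exactly where its 8-bit value is >= 128.
#'
#' @param path PNG file path.
#' @param pixel_size micrometres per pixel.
#' @param height_um channel height in micrometres.
#' @return a scene with no cells.
#' @export
load_mask <- function(path, pixel_size, height_um) {
  img <- png::readPNG(path)
  if (length(dim(img)) != 2L)
    stop("mask image must be single-channel greyscale")
  if (length(img) == 0L) stop("mask image is empty")
  mask <- img >= 127.5 / 255
  if (all(mask)) stop("mask is entirely solid")
  new_scene(mask, pixel_size = pixel_size, height_um = height_um,
            meta = list(source = path))
}

#' @rdname load_mask
#' @param scene a scene.
#' @export
save_mask <- function(scene, path) {
  png::writePNG(scene$mask * 1, path)
  invisible(path)
}
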