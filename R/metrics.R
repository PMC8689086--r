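#' Voronoi partition of the open space among cells and obstacles
#'
#' Assigns every open pixel of the analysis region to its nearest particle,
#' where the particles are (a) each cell, acting as a point generator at its
#' centre pixel, and (b) each 4-connected obstacle component that intersects
#' the analysis region, acting as an extended generator whose distance to a
#' pixel is the exact Euclidean distance to its nearest solid pixel. Regions
#' are returned for cells only; the space captured by obstacle generators is
#' reported in the `obstacle_area_px` attribute so that the partition can be
#' audited (cell areas + obstacle-assigned area = open area, no pixel lost).
#'
#' Ties are broken in favour of cells (a pixel equidistant between a cell
#' and an obstacle belongs to the cell) and, among cells, in favour of the
#' lowest cell id. Distances are compared as exact squared integers so tie
#' handling is deterministic.
#'
#' Obstacle components wholly outside the analysis region (for example the
#' pillar ring that bounds a trap) do not act as generators: the region
#' boundary clips the partition instead, mirroring how per-trap images are
#' analysed.
#'
#' @param scene a scene with at least one cell.
#' @return a list of `strucell_voronoi` regions (one per cell, in cell id
#'   order), each with `cell_id`, `centre`, `pixels` (2-column row/col
#'   matrix), `area_um2` and linear greyscale `grey` weights; the list
#'   carries attributes `obstacle_area_px` and `open_area_px`.
#' @export
voronoi_partition <- function(scene) {
  stopifnot(inherits(scene, "strucell_scene"))
  cl <- scene$cells
  if (nrow(cl) == 0L) stop("scene has no cells")
  cl <- cl[order(cl$id), , drop = FALSE]
  r <- scene$roi
  if (r[1] > r[2] || r[3] > r[4]) stop("empty analysis region")
  nr <- nrow(scene$mask); nc <- ncol(scene$mask)

  # obstacle generators: 4-connected components intersecting the ROI
  lab <- .label4_cpp(scene$mask)
  roi_labs <- setdiff(unique(as.vector(
    lab[r[1]:r[2], r[3]:r[4], drop = FALSE])), 0L)
  d2_obs <- if (length(roi_labs)) {
    gen <- matrix(lab %in% roi_labs, nr, nc)
    .edt_cpp(gen)$dist2
  } else matrix(Inf, nr, nc)

  np <- .nearest_point_cpp(nr, nc, cl$row, cl$col)
  # open ROI pixels; cells win exact ties against obstacles
  open <- matrix(FALSE, nr, nc)
  open[r[1]:r[2], r[3]:r[4]] <- !scene$mask[r[1]:r[2], r[3]:r[4]]
  to_cell <- open & (np$dist2 <= d2_obs)
  idx <- which(to_cell)
  assign_cell <- np$which[idx]
  regions <- lapply(seq_len(nrow(cl)), function(k) {
    pk <- idx[assign_cell == k]
    pixels <- cbind(row = (pk - 1L) %% nr + 1L, col = (pk - 1L) %/% nr + 1L)
    reg <- structure(list(
      cell_id = cl$id[k],
      centre = c(row = cl$row[k], col = cl$col[k]),
      pixels = pixels,
      area_um2 = nrow(pixels) * scene$pixel_size^2,
      grey = NULL), class = "strucell_voronoi")
    reg$grey <- grey_distance_map(reg)
    reg
  })
  attr(regions, "open_area_px") <- sum(open)
  attr(regions, "obstacle_area_px") <- sum(open) - length(idx)
  attr(regions, "pixel_size") <- scene$pixel_size
  regions
}

#' Linear greyscale distance map of a Voronoi region
#'
#' Weights every pixel of a region linearly by its exact Euclidean distance
#' (in pixels) from the cell-centre pixel, starting at 1: the centre pixel
#' itself weighs 1 and a pixel 200 pixels away weighs 201. Weights are kept
#' at full precision; they are clamped to 0..255 only when rendered as an
#' 8-bit image.
#'
#' @param region a `strucell_voronoi` region.
#' @param centre optional `c(row, col)` override of the cell centre.
#' @return numeric vector of weights, aligned with `region$pixels`.
#' @export
grey_distance_map <- function(region, centre = region$centre) {
  stopifnot(inherits(region, "strucell_voronoi"))
  if (nrow(region$pixels) == 0L) stop("empty region")
  sqrt((region$pixels[, 1] - centre[1])^2 +
       (region$pixels[, 2] - centre[2])^2) + 1
}

#' Summary spatial metrics of a Voronoi region
#'
#' Area (open pixels times `pixel_size^2`) and the mean, median and maximum
#' of the region's greyscale distance weights. The median of an even-sized
#' sample is the lower-middle order statistic, matching 8-bit image
#' histogram medians.
#'
#' @param region a `strucell_voronoi` region.
#' @param pixel_size micrometres per pixel.
#' @return one-row data frame: `cell_id`, `area_um2`, `mean_grey`,
#'   `median_grey`, `max_grey`.
#' @export
summarize_region <- function(region, pixel_size) {
  stopifnot(inherits(region, "strucell_voronoi"),
            nrow(region$pixels) > 0L)
  g <- region$grey
  data.frame(cell_id = region$cell_id,
             area_um2 = nrow(region$pixels) * pixel_size^2,
             mean_grey = mean(g),
             median_grey = median_low(g),
             max_grey = max(g))
}

# lower-middle median: the ceiling(n/2)-th order statistic
median_low <- function(x) sort(x)[ceiling(length(x) / 2)]

#' Spatial metrics table for every cell of a scene
#'
#' Runs [voronoi_partition()] and [summarize_region()] for all cells.
#'
#' @param scene a scene with cells.
#' @return data frame with one row per cell.
#' @export
spatial_metrics <- function(scene) {
  regions <- voronoi_partition(scene)
  do.call(rbind, lapply(regions, summarize_region,
                        pixel_size = scene$pixel_size))
}

#' Render Voronoi regions as images
#'
#' `voronoi_label_raster` returns an integer raster of cell ids (0 where a
#' pixel is solid, obstacle-assigned or outside the region of interest);
#' `grey_render` returns a greyscale distance-map image with weights clamped
#' to 0..255 and rescaled to `[0, 1]` (0 = white is rendered as 1 here, i.e.
#' darker pixels are farther, matching an inverted 8-bit export).
#'
#' @param scene the scene the regions came from.
#' @param regions result of [voronoi_partition()].
#' @return integer matrix of labels, or numeric image matrix.
#' @export
voronoi_label_raster <- function(scene, regions) {
  out <- matrix(0L, nrow(scene$mask), ncol(scene$mask))
  for (reg in regions) out[reg$pixels] <- reg$cell_id
  out
}

#' @rdname voronoi_label_raster
#' @export
grey_render <- function(scene, regions) {
  img <- matrix(0, nrow(scene$mask), ncol(scene$mask))
  for (reg in regions) img[reg$pixels] <- pmin(reg$grey, 255) / 255
  img
}
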