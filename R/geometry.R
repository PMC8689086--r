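#' Mock object arrays around a central cell
#'
#' Builds the systematic test images used to exercise the spatial metrics: a
#' single central cell surrounded by `n_objects` solid discs whose nearest
#' surface sits exactly `spacing` object-diameters from the cell centre.
#' Objects are placed deterministically clockwise starting directly above
#' the cell (at most 8, on the compass points), so identical specifications
#' yield identical masks.
#'
#' @param n_objects number of surrounding discs, 0..8.
#' @param spacing surface-to-cell-centre distance in object-diameters (1 or 2).
#' @param object_diameter object diameter, micrometres.
#' @param cell_diameter central cell diameter, micrometres.
#' @param extent_um side length of the square raster, micrometres.
#' @param pixel_size micrometres per pixel (default 0.5).
#' @return a scene with one cell and `n_objects` solid discs.
#' @examples
#' sc <- generate_mock_array(n_objects = 4, spacing = 1)
#' @export
generate_mock_array <- function(n_objects, spacing, object_diameter = 10,
                                cell_diameter = 4.5, extent_um = 150,
                                pixel_size = 0.5) {
  stopifnot(n_objects >= 0, n_objects <= 8, spacing %in% c(1, 2),
            object_diameter > 0, extent_um > 0)
  n_px <- round(extent_um / pixel_size)
  if (n_px %% 2 == 0) n_px <- n_px + 1L  # integer centre pixel
  ctr <- (n_px + 1) / 2
  d_px <- object_diameter / pixel_size
  # nearest object surface at spacing * diameter from the cell centre
  centre_dist <- spacing * d_px + d_px / 2
  if (ctr - centre_dist - d_px / 2 < 1)
    stop("geometry error: raster extent too small for the requested spacing")
  # clockwise from north; raster rows grow downwards
  ang <- (pi / 2) - (seq_len(8) - 1) * (pi / 4)
  mask <- matrix(FALSE, n_px, n_px)
  if (n_objects > 0) {
    for (k in seq_len(n_objects)) {
      # snap centres to the pixel grid so equal discs rasterise identically
      orow <- round(ctr - centre_dist * sin(ang[k]))
      ocol <- round(ctr + centre_dist * cos(ang[k]))
      px <- disc_pixels(orow, ocol, d_px / 2, n_px, n_px)
      if (any(mask[px]))
        stop("geometry error: objects overlap at this spacing")
      if (min((px[, 1] - ctr)^2 + (px[, 2] - ctr)^2) <=
          (cell_diameter / 2 / pixel_size)^2)
        stop("geometry error: object overlaps the central cell")
      mask[px] <- TRUE
    }
  }
  cells <- data.frame(id = 1L, row = round(ctr), col = round(ctr),
                      diameter_um = cell_diameter)
  new_scene(mask, pixel_size, height_um = 20, cells = cells,
            meta = list(generator = "mock_array", n_objects = n_objects,
                        spacing = spacing, object_diameter = object_diameter))
}

#' Pillar-bounded cell traps with microspheres
#'
#' Generates `n_traps` independent trap scenes emulating a commercial
#' microfluidic trap plate: a square trap interior (default 100 x 100 um)
#' bounded by a perimeter of square pillars with gaps that retain a cell
#' while letting medium flow through, seeded with 4-um microspheres and
#' exactly one cell per trap. The sphere count per trap is drawn from a
#' normal distribution truncated at zero (rounded to an integer); spheres
#' are placed uniformly in the trap interior without overlapping each other
#' or the pillars. The trap interior is the analysis region of each scene.
#'
#' @param n_traps number of traps to generate.
#' @param mean_spheres,sd_spheres truncated-normal parameters of the sphere
#'   count per trap.
#' @param trap_side trap interior side length, micrometres.
#' @param sphere_diameter microsphere diameter, micrometres.
#' @param pillar_size square pillar side, micrometres.
#' @param pillar_gap gap between pillars, micrometres.
#' @param margin open margin outside the pillar ring at the inlet/outlet
#'   edges, micrometres.
#' @param cell_diameter cell diameter, micrometres.
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed; realised counts and placements are
#'   deterministic under a fixed seed.
#' @return a list of scenes, one per trap, each with `meta$n_spheres`.
#' @export
generate_trap_chamber <- function(n_traps, mean_spheres, sd_spheres = 0,
                                  trap_side = 100, sphere_diameter = 4,
                                  pillar_size = 4, pillar_gap = 6,
                                  margin = 4, cell_diameter = 4.5,
                                  pixel_size = 0.5, seed = NULL) {
  stopifnot(n_traps >= 1, trap_side > 0, sphere_diameter > 0,
            mean_spheres >= 0, sd_spheres >= 0)
  with_seed(seed, {
    lapply(seq_len(n_traps), function(k) {
      n_s <- rtrunc_count(mean_spheres, sd_spheres)
      trap_scene(n_s, trap_side, sphere_diameter, pillar_size, pillar_gap,
                 margin, cell_diameter, pixel_size, seed, k)
    })
  })
}

# one count from a normal truncated at zero, rounded to an integer
rtrunc_count <- function(mean, sd) {
  if (sd == 0) return(as.integer(round(max(0, mean))))
  repeat {
    x <- rnorm(1, mean, sd)
    if (x > -0.5) return(as.integer(max(0, round(x))))
  }
}

trap_scene <- function(n_spheres, trap_side, sphere_diameter, pillar_size,
                       pillar_gap, margin, cell_diameter, pixel_size,
                       seed, index) {
  px <- function(um) round(um / pixel_size)
  side <- px(trap_side); ps <- px(pillar_size); mg <- px(margin)
  n_row <- side + 2L * (ps + mg)        # open margins at inlet and outlet
  n_col <- side + 2L * ps               # side walls close the flanks
  mask <- matrix(FALSE, n_row, n_col)
  # pillar band: frame of thickness ps around the interior, with gaps
  period <- px(pillar_size + pillar_gap)
  in_pillar <- function(along) (along - 1L) %% period < ps
  band_rows <- c(mg + seq_len(ps), mg + ps + side + seq_len(ps))
  band_cols <- c(seq_len(ps), ps + side + seq_len(ps))
  for (r in band_rows) mask[r, in_pillar(seq_len(n_col))] <- TRUE
  for (cc in band_cols) mask[in_pillar(seq_len(n_row)), cc] <- TRUE
  roi <- c(mg + ps + 1L, mg + ps + side, ps + 1L, ps + side)
  # spheres: uniform centres in the interior, fully inside it, no overlaps
  r_s <- sphere_diameter / 2 / pixel_size
  centres <- matrix(numeric(0), 0, 2)
  if (n_spheres > 0) {
    tries <- 0L
    while (nrow(centres) < n_spheres) {
      if ((tries <- tries + 1L) > 4000L * n_spheres)
        stop("geometry error: could not pack the requested sphere count")
      cand <- c(runif(1, roi[1] - 1 + r_s, roi[2] - r_s + 1),
                runif(1, roi[3] - 1 + r_s, roi[4] - r_s + 1))
      if (nrow(centres) == 0 ||
          all((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2 >=
              (2 * r_s)^2))
        centres <- rbind(centres, cand)
    }
    for (k in seq_len(nrow(centres)))
      mask <- add_disc(mask, centres[k, 1], centres[k, 2], r_s)
  }
  scene <- new_scene(mask, pixel_size, height_um = 4,
                     roi = roi,
                     meta = list(generator = "trap_chamber", trap = index,
                                 n_spheres = n_spheres, seed = seed,
                                 sphere_centres_px = centres,
                                 sphere_radius_px = r_s))
  place_cells(scene, 1L, min_clearance = 0.25, diameter = cell_diameter,
              seed = NULL)  # draws from the surrounding seeded stream
}

#' Soil-micromodel-like channel
#'
#' Generates a statistical stand-in for a soil micromodel: a straight
#' channel populated with randomly placed, possibly overlapping elliptical
#' particles until a target porosity (open-area fraction over the whole
#' channel) is reached. The published micromodel pore layout itself is not
#' reproduced; this generator only matches its scale and statistical
#' character. Clear margins are kept at the inlet (top) and outlet (bottom)
#' edges, and the generated scene is checked for an open inlet-to-outlet
#' path.
#'
#' @param width_um channel width, micrometres (default 1000).
#' @param length_um channel length, micrometres (default 2000, about one
#'   fifth of the full 10 mm device).
#' @param height_um structure height, micrometres (default 32).
#' @param target_porosity target open-area fraction of the whole channel
#'   raster, in (0, 1]. The obstacle-free margins are part of the raster, so
#'   they must stay small relative to the length for low targets to be
#'   reachable.
#' @param particle_axes range of full ellipse axes, micrometres.
#' @param margin_um obstacle-free margin at inlet and outlet, micrometres.
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @return a scene (no cells; see [place_cells()]).
#' @export
generate_micromodel <- function(width_um = 1000, length_um = 2000,
                                height_um = 32, target_porosity = 0.55,
                                particle_axes = c(15, 60), margin_um = 25,
                                pixel_size = 0.5, seed = NULL) {
  stopifnot(target_porosity > 0, target_porosity <= 1, width_um > 0,
            length_um > 2 * margin_um)
  n_row <- round(length_um / pixel_size)
  n_col <- round(width_um / pixel_size)
  mg <- round(margin_um / pixel_size)
  n_px <- as.double(n_row) * n_col
  with_seed(seed, {
    scene <- NULL
    # a dense packing can occasionally block the channel; redraw (bounded,
    # within the same seeded stream, so results stay deterministic)
    for (attempt in 1:25) {
      mask <- matrix(FALSE, n_row, n_col)
      solid_px <- 0
      guard <- 0L
      while (1 - solid_px / n_px > target_porosity) {
        if ((guard <- guard + 1L) > 50000L)
          stop("geometry error: target porosity unreachable")
        a <- runif(1, particle_axes[1], particle_axes[2]) / 2 / pixel_size
        b <- runif(1, particle_axes[1], particle_axes[2]) / 2 / pixel_size
        th <- runif(1, 0, pi)
        r0 <- runif(1, mg + a, n_row - mg - a)
        c0 <- runif(1, 1, n_col)
        res <- add_ellipse(mask, r0, c0, a, b, th, count = TRUE)
        mask <- res$mask
        solid_px <- solid_px + res$added  # ellipses may overlap
      }
      cand <- new_scene(mask, pixel_size, height_um,
                        meta = list(generator = "micromodel", seed = seed,
                                    target_porosity = target_porosity,
                                    attempt = attempt))
      ok <- tryCatch({ validate_scene(cand); TRUE },
                     error = function(e) FALSE)
      if (ok) { scene <- cand; break }
    }
    if (is.null(scene))
      stop("geometry error: could not generate a percolating micromodel")
    scene
  })
}

# paint a solid filled ellipse (semi-axes a, b px, rotation th) into a mask;
# with count = TRUE also report how many pixels turned solid
add_ellipse <- function(mask, r0, c0, a, b, th, count = FALSE) {
  ext <- max(a, b)
  rr <- max(1L, floor(r0 - ext)):min(nrow(mask), ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(ncol(mask), ceiling(c0 + ext))
  dr <- outer(rr - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - c0)
  x <- dc * cos(th) + dr * sin(th)
  y <- -dc * sin(th) + dr * cos(th)
  inside <- (x / a)^2 + (y / b)^2 <= 1
  sub <- mask[rr, cc, drop = FALSE]
  mask[rr, cc] <- sub | inside
  if (!count) return(mask)
  list(mask = mask, added = sum(inside & !sub))
}
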