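test_that("mock arrays are deterministic and placed at the stated spacing", {
  a <- generate_mock_array(n_objects = 5, spacing = 2)
  b <- generate_mock_array(n_objects = 5, spacing = 2)
  expect_identical(a$mask, b$mask)
  expect_identical(a$cells, b$cells)

  # no objects: the raster is fully open (cells never enter the mask)
  empty <- generate_mock_array(n_objects = 0, spacing = 1)
  expect_false(any(empty$mask))
  expect_equal(nrow(empty$cells), 1L)

  # one object: nearest solid surface one object-diameter from cell centre
  one <- generate_mock_array(n_objects = 1, spacing = 1, object_diameter = 10)
  solid <- which(one$mask, arr.ind = TRUE)
  ctr <- unlist(one$cells[1, c("row", "col")])
  d_px <- sqrt(min((solid[, 1] - ctr[1])^2 + (solid[, 2] - ctr[2])^2))
  expect_equal(d_px * one$pixel_size, 10, tolerance = 0.05)

  # eight objects at the wider spacing: no overlaps, so the solid pixel
  # count is exactly eight single discs
  single <- sum(generate_mock_array(1, 2)$mask)
  eight <- sum(generate_mock_array(8, 2)$mask)
  expect_equal(eight, 8L * single)
})

test_that("mock arrays error out when the raster cannot hold the objects", {
  expect_error(generate_mock_array(2, 2, object_diameter = 40,
                                   extent_um = 100),
               "geometry error")
})

test_that("trap sphere counts follow the truncated normal", {
  traps <- generate_trap_chamber(500, mean_spheres = 39, sd_spheres = 8,
                                 seed = 101)
  counts <- vapply(traps, function(s) s$meta$n_spheres, integer(1))
  expect_true(all(counts >= 0))
  # mean within 3 SE, sd close to nominal (truncation at 0 is negligible
  # at mean/sd ~ 5)
  expect_lt(abs(mean(counts) - 39), 3 * 8 / sqrt(500))
  expect_lt(abs(sd(counts) - 8), 1.2)
  # rounding-to-integer symmetry: distribution is not skewed by clamping
  expect_lt(abs(median(counts) - 39), 2)
})

test_that("spheres sit inside the trap without touching pillars or spheres", {
  traps <- generate_trap_chamber(15, mean_spheres = 39, sd_spheres = 8,
                                 seed = 7)
  for (s in traps) {
    ctr <- s$meta$sphere_centres_px
    if (is.null(ctr) || nrow(ctr) == 0) next
    r_s <- s$meta$sphere_radius_px
    # pillar-only raster: remove the spheres from the mask
    pillars <- s$mask
    for (k in seq_len(nrow(ctr)))
      pillars[strucell:::disc_pixels(ctr[k, 1], ctr[k, 2], r_s, nrow(pillars),
                          ncol(pillars))] <- FALSE
    d2 <- strucell:::.edt_cpp(pillars)$dist2
    ctr_px <- cbind(round(ctr[, 1]), round(ctr[, 2]))
    expect_true(all(sqrt(d2[ctr_px]) >= r_s - 1))
    if (nrow(ctr) > 1)
      expect_true(min(dist(ctr)) >= 2 * r_s - 1e-9)
  }
})

test_that("every trap holds exactly one cell on open interior space", {
  traps <- generate_trap_chamber(10, mean_spheres = 16, sd_spheres = 5,
                                 seed = 3)
  for (s in traps) {
    expect_equal(nrow(s$cells), 1L)
    expect_silent(validate_scene(s))
  }
})

test_that("zero-sphere traps contain only the pillar perimeter and a cell", {
  traps <- generate_trap_chamber(3, mean_spheres = 0, seed = 5)
  for (s in traps) {
    r <- s$roi
    expect_false(any(s$mask[r[1]:r[2], r[3]:r[4]]))  # interior fully open
    expect_true(any(s$mask))                          # pillars exist
    expect_equal(s$meta$n_spheres, 0L)
  }
})

test_that("micromodels hit the target porosity and stay connected", {
  mm <- generate_micromodel(width_um = 250, length_um = 500,
                            target_porosity = 0.5, pixel_size = 1, seed = 2)
  expect_lt(abs(open_fraction(mm) - 0.5), 0.05)
  expect_silent(validate_scene(mm))
  # determinism
  mm2 <- generate_micromodel(width_um = 250, length_um = 500,
                             target_porosity = 0.5, pixel_size = 1, seed = 2)
  expect_identical(mm$mask, mm2$mask)
  # an empty channel is porosity 1
  e <- generate_micromodel(width_um = 100, length_um = 200,
                           target_porosity = 1, pixel_size = 1, seed = 1)
  expect_false(any(e$mask))
})

test_that("generated scenes satisfy their invariants across seeds", {
  for (seed in 1:100) {
    s <- generate_trap_chamber(1, mean_spheres = 20, sd_spheres = 10,
                               seed = seed)[[1]]
    expect_silent(validate_scene(s))
  }
  for (seed in 1:100) {
    # smaller particles on this small test raster so a single particle
    # cannot overshoot the porosity tolerance
    mm <- generate_micromodel(width_um = 120, length_um = 240,
                              target_porosity = 0.55, pixel_size = 1,
                              particle_axes = c(10, 30), seed = seed)
    expect_silent(validate_scene(mm))
    expect_lt(abs(open_fraction(mm) - 0.55), 0.05)
  }
})

test_that("place_cells samples open clear pixels reproducibly", {
  mm <- generate_micromodel(width_um = 200, length_um = 400,
                            target_porosity = 0.6, pixel_size = 1, seed = 9)
  expect_identical(place_cells(mm, 0), mm)
  a <- place_cells(mm, 50, seed = 4)
  b <- place_cells(mm, 50, seed = 4)
  expect_identical(a$cells, b$cells)
  expect_equal(nrow(a$cells), 50L)
  expect_false(any(a$mask[cbind(a$cells$row, a$cells$col)]))
  expect_false(anyDuplicated(a$cells[, c("row", "col")]) > 0)
  # clearance: no solid pixel within the cell radius
  d2 <- strucell:::.edt_cpp(a$mask)$dist2
  r_need <- (a$cells$diameter_um / 2) / a$pixel_size
  expect_true(all(d2[cbind(a$cells$row, a$cells$col)] > r_need^2))
  expect_error(place_cells(mm, 1e6, seed = 1), "placement error")
})

test_that("masks round-trip through PNG bit-exactly", {
  tr <- generate_trap_chamber(1, 16, 5, seed = 12)[[1]]
  dir <- withr::local_tempdir()
  save_scene(tr, dir)
  back <- load_scene(dir)
  expect_identical(back$mask, tr$mask)
  expect_equal(back$cells$row, tr$cells$row)
  expect_equal(back$roi, tr$roi)
  expect_equal(back$pixel_size, tr$pixel_size)
})

test_that("mask loading binarises 8-bit images at 128", {
  dir <- withr::local_tempdir()
  img <- matrix(c(0, 127, 128, 255) / 255, 2, 2)
  png::writePNG(img, file.path(dir, "m.png"))
  sc <- load_mask(file.path(dir, "m.png"), pixel_size = 1, height_um = 10)
  expect_identical(as.vector(sc$mask), c(FALSE, FALSE, TRUE, TRUE))
  # an all-zero image has no obstacles
  png::writePNG(matrix(0, 4, 4), file.path(dir, "z.png"))
  expect_false(any(load_mask(file.path(dir, "z.png"), 1, 10)$mask))
  # an all-solid mask is rejected
  png::writePNG(matrix(1, 4, 4), file.path(dir, "s.png"))
  expect_error(load_mask(file.path(dir, "s.png"), 1, 10), "solid")
})
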