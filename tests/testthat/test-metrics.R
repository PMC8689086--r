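test_that("voronoi assignment matches the exhaustive oracle", {
  set.seed(31)
  for (rep in 1:6) {
    mask <- matrix(FALSE, 64, 64)
    for (k in 1:3) {
      ctr <- runif(2, 10, 54)
      mask <- strucell:::add_disc(mask, ctr[1], ctr[2], runif(1, 2, 6))
    }
    open <- which(!mask, arr.ind = TRUE)
    pick <- open[sample(nrow(open), 4), ]
    sc <- new_scene(mask, pixel_size = 0.5, height_um = 10,
                    cells = data.frame(id = 1:4, row = pick[, 1],
                                       col = pick[, 2], diameter_um = 4.5))
    regions <- voronoi_partition(sc)
    lab <- voronoi_label_raster(sc, regions)
    expect_identical(lab, brute_voronoi(sc))
  }
})

test_that("a single cell with no obstacles owns the whole open region", {
  sc <- new_scene(matrix(FALSE, 40, 50), pixel_size = 0.5, height_um = 10,
                  cells = data.frame(id = 1L, row = 20L, col = 25L,
                                     diameter_um = 4.5))
  regions <- voronoi_partition(sc)
  expect_equal(nrow(regions[[1]]$pixels), 40L * 50L)
  expect_equal(regions[[1]]$area_um2, 40 * 50 * 0.25)
  expect_equal(attr(regions, "obstacle_area_px"), 0L)
})

test_that("the partition loses no pixels and never double-counts", {
  sc <- generate_mock_array(6, 1)
  sc$cells <- rbind(sc$cells,
                    data.frame(id = 2L, row = 30L, col = 30L,
                               diameter_um = 4.5))
  regions <- voronoi_partition(sc)
  n_cell_px <- sum(vapply(regions, function(r) nrow(r$pixels), numeric(1)))
  expect_equal(n_cell_px + attr(regions, "obstacle_area_px"),
               attr(regions, "open_area_px"))
  lab <- voronoi_label_raster(sc, regions)
  expect_true(all(table(lab[lab > 0]) ==
                  vapply(regions, function(r) nrow(r$pixels), numeric(1))))
})

test_that("grey distance maps weight linearly from 1 at the centre", {
  sc <- new_scene(matrix(FALSE, 512, 512), pixel_size = 0.5, height_um = 10,
                  cells = data.frame(id = 1L, row = 256L, col = 156L,
                                     diameter_um = 4.5))
  reg <- voronoi_partition(sc)[[1]]
  w <- reg$grey
  centre_idx <- which(reg$pixels[, 1] == 256 & reg$pixels[, 2] == 156)
  expect_equal(w[centre_idx], 1)
  # a pixel exactly 200 pixels away along an axis weighs 201
  far_idx <- which(reg$pixels[, 1] == 256 & reg$pixels[, 2] == 356)
  expect_equal(w[far_idx], 201)
  # full direct enumeration on a small region
  sc2 <- new_scene(matrix(FALSE, 32, 32), pixel_size = 0.5, height_um = 10,
                   cells = data.frame(id = 1L, row = 10L, col = 22L,
                                      diameter_um = 4.5))
  reg2 <- voronoi_partition(sc2)[[1]]
  direct <- sqrt((reg2$pixels[, 1] - 10)^2 + (reg2$pixels[, 2] - 22)^2) + 1
  expect_equal(reg2$grey, direct)
  expect_true(all(reg2$grey >= 1))
})

test_that("region summaries use the lower-middle median and exact means", {
  sc <- new_scene(matrix(FALSE, 32, 32), pixel_size = 0.5, height_um = 10,
                  cells = data.frame(id = 1L, row = 16L, col = 16L,
                                     diameter_um = 4.5))
  reg <- voronoi_partition(sc)[[1]]
  s <- summarize_region(reg, sc$pixel_size)
  expect_equal(s$mean_grey, mean(reg$grey))
  expect_equal(s$median_grey, sort(reg$grey)[ceiling(length(reg$grey) / 2)])
  expect_true(s$median_grey <= s$max_grey && s$mean_grey <= s$max_grey)
  # lower-middle convention on an even count
  expect_equal(strucell:::median_low(c(1, 2, 3, 10)), 2)
  expect_equal(strucell:::median_low(c(5, 1, 9)), 5)
  # single-pixel region
  one <- structure(list(cell_id = 1L, centre = c(row = 3, col = 3),
                        pixels = cbind(row = 3L, col = 3L),
                        grey = 1, area_um2 = 0.25),
                   class = "strucell_voronoi")
  s1 <- summarize_region(one, 0.5)
  expect_equal(s1$area_um2, 0.25)
  expect_equal(s1$mean_grey, 1)
  expect_equal(s1$median_grey, 1)
})

test_that("whole-pixel translation translates the regions identically", {
  base <- matrix(FALSE, 48, 48)
  base <- strucell:::add_disc(base, 15, 30, 4)
  sc <- new_scene(base, pixel_size = 0.5, height_um = 10,
                  cells = data.frame(id = 1L, row = 25L, col = 20L,
                                     diameter_um = 4.5))
  shifted_mask <- matrix(FALSE, 48, 48)
  shifted_mask[6:48, 4:48] <- base[1:43, 1:45]
  sc2 <- new_scene(shifted_mask, pixel_size = 0.5, height_um = 10,
                   cells = data.frame(id = 1L, row = 30L, col = 23L,
                                      diameter_um = 4.5),
                   roi = c(6L, 48L, 4L, 48L))
  sc$roi <- c(1L, 43L, 1L, 45L)
  r1 <- voronoi_partition(sc)[[1]]
  r2 <- voronoi_partition(sc2)[[1]]
  expect_equal(nrow(r1$pixels), nrow(r2$pixels))
  expect_equal(r1$pixels[, 1] + 5L, r2$pixels[, 1])
  expect_equal(r1$pixels[, 2] + 3L, r2$pixels[, 2])
  expect_equal(r1$grey, r2$grey)
})

test_that("adding objects never grows the cell's area (mock progression)", {
  for (spacing in c(1, 2)) {
    areas <- vapply(0:8, function(n)
      spatial_metrics(generate_mock_array(n, spacing))$area_um2, numeric(1))
    expect_true(all(diff(areas) <= 1e-9))
    greys <- vapply(0:8, function(n)
      spatial_metrics(generate_mock_array(n, spacing))$mean_grey, numeric(1))
    # the grey summaries follow the trend with small permitted deviations
    expect_lt(cor(0:8, greys, method = "spearman"), -0.9)
    expect_lt(greys[9], 0.2 * greys[1])
  }
  # closer objects shrink the area more than distant ones
  a1 <- spatial_metrics(generate_mock_array(4, 1))$area_um2
  a2 <- spatial_metrics(generate_mock_array(4, 2))$area_um2
  expect_lt(a1, a2)
})

test_that("the exact distance transform agrees with an independent library", {
  skip_if_not_installed("EBImage")
  set.seed(13)
  for (rep in 1:3) {
    m <- matrix(runif(60 * 50) < 0.08, 60, 50)
    if (!any(m)) next
    ours <- sqrt(strucell:::.edt_cpp(m)$dist2)
    ref <- EBImage::distmap(EBImage::Image(1 - m * 1), metric = "euclidean")
    expect_equal(ours, as.matrix(ref@.Data), ignore_attr = TRUE)
  }
})

test_that("degenerate inputs are rejected", {
  sc <- new_scene(matrix(FALSE, 8, 8), pixel_size = 1, height_um = 10)
  expect_error(voronoi_partition(sc), "no cells")
  reg <- structure(list(cell_id = 1L, centre = c(row = 1, col = 1),
                        pixels = matrix(integer(), 0, 2), grey = numeric()),
                   class = "strucell_voronoi")
  expect_error(grey_distance_map(reg), "empty")
})
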