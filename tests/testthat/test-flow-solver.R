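# The closed-form channel profile is the solver's primary oracle: an empty
# straight channel admits the analytic cross-channel solution
# v(x) = V [1 - cosh(sqrt(12) x'/h) / cosh(sqrt(12) w/(2h))]
# whose limits are the plane parabola (h >> w) and a plug (h << w).
# Profiles are compared outside the near-wall layer of width h/sqrt(12)
# (at least one pixel), which the staircase discretisation cannot resolve
# pointwise.

test_that("the straight channel matches the Brinkman closed form", {
  sc <- channel_scene(nx = 64, ny = 96, height_px = 4)
  f <- solve_flow(sc, v0 = 1e-5)
  expect_lt(profile_error(f, 4), 0.02)
})

test_that("thin and thick limits are recovered", {
  # thin (h << w): plug profile, cross-section mean equal to v0
  f_thin <- solve_flow(channel_scene(64, 96, height_px = 1), v0 = 1e-5)
  prof <- f_thin$v_face[49, ]
  expect_lt(abs(max(prof) / mean(prof) - 1), 0.02)
  expect_lt(abs(mean(prof) - 1), 1e-6)  # lattice units of v0
  # thick (h >> w): plane-Poiseuille parabola, peak/mean 3/2
  f_thick <- solve_flow(channel_scene(32, 128, height_px = 1e7), v0 = 1e-5)
  prof2 <- f_thick$v_face[65, ]
  expect_lt(abs(max(prof2) / mean(prof2) - 1.5), 0.02 * 1.5)
})

test_that("grid refinement converges to the closed form", {
  errs <- vapply(c(4, 8, 16), function(hpx) {
    f <- solve_flow(channel_scene(16 * hpx, 20 * hpx, height_px = hpx),
                    v0 = 1e-5)
    profile_error(f, hpx)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))          # monotone decrease
  expect_gt(errs[1] / errs[2], 2)           # at least first order
  expect_gt(errs[2] / errs[3], 2)
})

test_that("mass is conserved through every cross-section", {
  tr <- generate_trap_chamber(1, 16, 5, seed = 21)[[1]]
  f <- solve_flow(tr, physical_params(), v0 = 1.78e-5)
  fluxes <- vapply(seq_len(nrow(f$v_face)), function(s)
    cross_section_flux(f, s), numeric(1))
  expect_lt(max(abs(fluxes - fluxes[1])) / abs(fluxes[1]), 1e-6)
  # the imposed inlet flux is v0 * open inlet width * h
  open_w <- sum(!tr$mask[1, ]) * tr$pixel_size * 1e-6
  expect_equal(fluxes[1], 1.78e-5 * open_w * tr$height_um * 1e-6,
               tolerance = 1e-9)
  expect_error(cross_section_flux(f, 1e6), "outside")
})

test_that("converged solutions have pointwise divergence below tolerance", {
  mm <- generate_micromodel(width_um = 100, length_um = 200,
                            target_porosity = 0.6, pixel_size = 0.5,
                            particle_axes = c(10, 30), seed = 5)
  f <- solve_flow(mm, physical_params(), tol = 1e-10)
  ny <- nrow(mm$mask); nx <- ncol(mm$mask)
  div <- f$u_face[, 2:(nx + 1)] - f$u_face[, 1:nx] +
    f$v_face[2:(ny + 1), ] - f$v_face[1:ny, ]
  div[mm$mask] <- 0
  expect_lt(max(abs(div)), 1e-9)
  # speed is non-negative and exactly zero on solid pixels
  expect_true(all(f$speed >= 0))
  expect_true(all(f$speed[mm$mask] == 0))
  expect_true(all(is.na(f$pressure[mm$mask])))
})

test_that("neighbourhood speed averages open pixels within the radius", {
  sc <- channel_scene(40, 60, height_px = 8, pixel_size = 1)
  f <- solve_flow(sc, v0 = 1e-5)
  site <- c(30, 20)
  # direct enumeration oracle
  px <- expand.grid(row = 1:60, col = 1:40)
  keep <- (px$row - site[1])^2 + (px$col - site[2])^2 <= 7^2
  want <- mean(f$speed[as.matrix(px[keep, ])])
  expect_equal(neighbourhood_mean_speed(f, site, radius_um = 7), want)
  # uniform synthetic field: the mean is the field value at any radius
  uni <- f
  uni$speed <- matrix(3.3e-5, 60, 40)
  uni$mask <- matrix(FALSE, 60, 40)
  for (r in c(2, 5, 11))
    expect_equal(neighbourhood_mean_speed(uni, site, r), 3.3e-5)
  # the default radius is the advection-diffusion crossover D/v ~ 7 um
  expect_equal(formals(neighbourhood_mean_speed)$radius_um, 7)
})

test_that("a cell in a dead-end side pocket sees almost no flow", {
  mask <- matrix(FALSE, 80, 40)
  mask[20:60, 25:40] <- TRUE       # block the right side...
  mask[35:45, 25:36] <- FALSE      # ...except a deep pocket open on the left
  sc <- new_scene(mask, pixel_size = 1, height_um = 8)
  f <- solve_flow(sc, v0 = 1e-5)
  pocket <- neighbourhood_mean_speed(f, c(40, 34), radius_um = 3)
  channel <- neighbourhood_mean_speed(f, c(40, 12), radius_um = 3)
  expect_lt(pocket, 0.02 * channel)
})

test_that("a fully blocked channel raises a no-flow error", {
  mask <- matrix(FALSE, 30, 20)
  mask[15, ] <- TRUE
  sc <- new_scene(mask, pixel_size = 1, height_um = 8)
  expect_error(solve_flow(sc), "4-connected path|no-flow")
})
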