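test_that("percent increase follows the background-corrected formula", {
  expect_equal(percent_increase(100, 200, 0), 100)
  expect_equal(percent_increase(150, 150, 50), 0)
  expect_equal(percent_increase(150, 450, 50), 300)
  expect_error(percent_increase(50, 100, 60), "positive")
})

test_that("the dose-response model is linear with a first-step jump", {
  m <- dose_response_model()
  conc <- seq(25, 300, by = 25)
  mu <- expected_fluorescence(m, conc)
  fit <- linear_fit(conc, mu)
  expect_gt(fit$r_squared, 0.999)          # exactly linear over the range
  # the 0 -> 25 uM step exceeds the subsequent 25 uM increments
  step0 <- expected_fluorescence(m, 25) - expected_fluorescence(m, 0)
  step1 <- expected_fluorescence(m, 50) - expected_fluorescence(m, 25)
  expect_gt(step0, step1)
  # 2 h responses dominate 1 h at every concentration
  expect_true(all(expected_fluorescence(m, conc, "2h") >=
                  expected_fluorescence(m, conc, "1h")))
  # noiseless flask simulation sits on the model line
  med <- vapply(conc, function(cc)
    median(simulate_flask(50, cc, m, cv_percent = 0, seed = 1)), numeric(1))
  expect_gt(linear_fit(conc, med)$r_squared, 0.99)
})

test_that("flask noise reproduces the configured lognormal CV", {
  x <- simulate_flask(10000, 100, cv_percent = 63.8, seed = 42)
  expect_lt(abs(cv_percent(x) / 63.8 - 1), 0.03)
  expect_equal(mean(x), expected_fluorescence(dose_response_model(), 100),
               tolerance = 0.03)
  # cv = 0 collapses to the model mean
  expect_true(all(simulate_flask(10, 100, cv_percent = 0, seed = 1) ==
                  expected_fluorescence(dose_response_model(), 100)))
  # determinism
  expect_identical(simulate_flask(100, 50, seed = 7),
                   simulate_flask(100, 50, seed = 7))
})

test_that("moderate presets recover their population CV at large n", {
  for (nm in c("micromodel_uncoupled", "flask")) {
    p <- preset(nm)
    cells <- data.frame(cell_id = 1:10000)
    r <- simulate_structured(cells, p, seed = 11)
    expect_lt(abs(cv_percent(r$percent_increase) / p$cv_percent - 1), 0.03)
  }
  # heavy-tailed anchors: the moment CV estimator converges too slowly to
  # test directly, but the log-scale sigma is exact at any n
  pa <- preset("cellasic_area")
  cells <- data.frame(cell_id = 1:20000, area_um2 = rep(188, 20000))
  r <- simulate_structured(cells, pa, seed = 12)
  cv_target <- preset_cv(pa, 188) / 100
  sigma <- sqrt(log(1 + cv_target^2))
  expect_lt(abs(sd(log(r$percent_increase)) / sigma - 1), 0.03)
})

test_that("simulated fluorescence tables are self-consistent", {
  cells <- data.frame(cell_id = 1:50, area_um2 = runif(50, 100, 9000))
  r <- simulate_structured(cells, "cellasic_area", seed = 3)
  expect_equal(percent_increase(r$pre_fluor, r$post_fluor, r$background),
               r$percent_increase)
  expect_identical(r, simulate_structured(cells, "cellasic_area", seed = 3))
})

test_that("the area-coupled response rises through the 3000-6000 um2 window", {
  p <- preset("cellasic_area")
  a <- seq(100, 12000, by = 100)
  mu <- expected_percent_increase(p, area_um2 = a)
  expect_true(all(diff(mu) > 0))            # monotone increasing
  # the largest marginal increase lies inside the window
  expect_true(a[which.max(diff(mu))] > 3000 &&
              a[which.max(diff(mu))] < 6000)
  # flat above the window: beyond ~8000 um2 the response changes by < 1%
  expect_lt(mu[length(mu)] / mu[a == 8000] - 1, 0.01)
  # 10-90% of the dynamic range spans the window bounds
  lg <- (mu - p$floor_pct) / (p$ceiling_pct - p$floor_pct)
  expect_equal(a[which.min(abs(lg - 0.1))], 3000, tolerance = 0.05)
  expect_equal(a[which.min(abs(lg - 0.9))], 6000, tolerance = 0.05)
})

test_that("noise CV decreases with Voronoi area (binned)", {
  p <- preset("cellasic_area")
  a <- seq(200, 10000, by = 200)
  cvs <- preset_cv(p, a)
  expect_true(all(diff(cvs) <= 0))
  # realised per-bin CVs follow suit on simulated data
  set.seed(8)
  cells <- data.frame(cell_id = seq_len(6000),
                      area_um2 = runif(6000, 100, 10000))
  r <- simulate_structured(cells, p, seed = 8)
  b <- bin_by_area(r$area_um2, r$percent_increase, width = 2500)
  cv_seq <- b$cv_percent[b$count > 100]
  expect_true(all(diff(cv_seq) < 0))
})

test_that("halving every neighbourhood speed cuts the mean response by 34%", {
  p <- preset("cellasic_flow")
  expect_equal(p$alpha, log(1 - 0.34) / log(0.5))
  s <- runif(200, 2e-5, 3e-4)
  mu_full <- expected_percent_increase(p, nbhd_speed = s)
  mu_half <- expected_percent_increase(p, nbhd_speed = s / 2)
  expect_equal(100 * (1 - mean(mu_half) / mean(mu_full)), 34,
               tolerance = 1e-10)
})

test_that("the uncoupled null shows no area correlation on average", {
  set.seed(19)
  r_vals <- vapply(1:200, function(k) {
    cells <- data.frame(cell_id = 1:103, area_um2 = runif(103, 50, 9000))
    resp <- simulate_structured(cells, "micromodel_uncoupled",
                                seed = 1000 + k)
    pearson(resp$area_um2, resp$percent_increase)$r
  }, numeric(1))
  expect_lt(abs(mean(r_vals)), 0.03)
})

test_that("fitting the saturating curve recovers the response window", {
  p <- preset("cellasic_area")
  set.seed(5)
  a <- runif(20000, 200, 11000)
  mu <- expected_percent_increase(p, area_um2 = a)
  y <- mu * rlnorm(20000, -0.5 * log(1.09), sqrt(log(1.09)))  # mild noise
  fit <- minpack.lm::nlsLM(
    y ~ fl + (cl - fl) / (1 + exp(-(a - mid) / wd)),
    start = list(fl = 10, cl = 150, mid = 3000, wd = 400),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- coef(fit)
  lo <- est[["mid"]] - log(9) * est[["wd"]]
  hi <- est[["mid"]] + log(9) * est[["wd"]]
  expect_lt(abs(lo / 3000 - 1), 0.1)
  expect_lt(abs(hi / 6000 - 1), 0.1)
})

test_that("preset plumbing validates its inputs", {
  expect_error(preset("nope"), "unknown")
  expect_error(simulate_structured(data.frame(cell_id = 1),
                                   "cellasic_area"), "area_um2")
  expect_error(simulate_structured(data.frame(cell_id = 1),
                                   "cellasic_flow"), "nbhd_speed")
  expect_error(simulate_flask(10, 100, cv_percent = -5), "negative|cv")
})
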