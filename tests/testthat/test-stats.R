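test_that("cv_percent matches hand values and is scale invariant", {
  expect_equal(cv_percent(rep(4, 10)), 0)
  expect_equal(cv_percent(c(1, 3)), 100 * sqrt(2) / 2)
  set.seed(1)
  x <- rlnorm(100, 1, 0.4)
  expect_equal(cv_percent(3.7 * x), cv_percent(x))
  expect_error(cv_percent(5), "two values")
  expect_error(cv_percent(c(-2, 1)), "positive")
})

test_that("pearson agrees with the reference implementation", {
  set.seed(2)
  for (k in 1:100) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    got <- pearson(x, y)
    ref <- cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-10)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
    expect_equal(got$r_squared, got$r^2)
  }
  # exact linear relationship
  x <- 1:10
  expect_equal(pearson(x, 2 * x + 1)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  # symmetry and affine invariance
  set.seed(3); x <- rnorm(30); y <- rnorm(30)
  expect_equal(pearson(x, y)$r, pearson(y, x)$r)
  expect_equal(pearson(5 * x - 2, y)$r, pearson(x, y)$r)
  expect_equal(pearson(-x, y)$r, -pearson(x, y)$r)
  expect_error(pearson(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(pearson(1:2, 2:3), "at least 3")
})

test_that("linear_fit matches lm and the pearson identity", {
  set.seed(4)
  x <- runif(40, 0, 10); y <- 2.5 * x + rnorm(40)
  got <- linear_fit(x, y)
  ref <- lm(y ~ x)
  expect_equal(got$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(got$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(got$r_squared, summary(ref)$r.squared, tolerance = 1e-10)
  expect_equal(got$r_squared, pearson(x, y)$r_squared, tolerance = 1e-12)
  expect_equal(linear_fit(x, 3 * x - 1)$r_squared, 1)
  expect_error(linear_fit(rep(2, 5), rnorm(5)), "degenerate")
})

test_that("area binning is half-open from zero with SEM and CV", {
  a <- c(500, 999.999, 1000, 1500, 3200)
  y <- c(10, 20, 30, 40, 50)
  b <- bin_by_area(a, y, width = 1000)
  expect_equal(b$count, c(2L, 2L, 0L, 1L))
  expect_equal(b$mean[1], 15)
  expect_equal(b$mean[2], 35)         # the edge value 1000 went up
  expect_true(is.na(b$mean[3]))
  expect_equal(b$sem[1], sd(c(10, 20)) / sqrt(2))
  expect_equal(sum(b$count), length(a))
  expect_equal(b$bin_lo, c(0, 1000, 2000, 3000))
  # grouped recomputation oracle
  set.seed(5)
  a2 <- runif(500, 0, 8000); y2 <- rnorm(500, 50, 5)
  b2 <- bin_by_area(a2, y2)
  ref <- tapply(y2, floor(a2 / 1000), mean)
  expect_equal(b2$mean[b2$count > 0], as.vector(ref), tolerance = 1e-12)
  expect_equal(sum(b2$count), 500L)
  expect_error(bin_by_area(c(-1, 2), c(1, 2)), "negative")
})
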