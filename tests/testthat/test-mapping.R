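test_that("equal-interval classification uses arithmetic breakpoints", {
  g <- lai_grid(matrix(seq(0, 1, length.out = 100), 10, 10))
  cls <- classify_ndvi(g, k = 5)
  expect_equal(cls$class_bounds, seq(0, 1, by = 0.2))
  expect_true(all(diff(cls$class_bounds) > 0))
  expect_equal(sum(cls$class_counts), 100)
  expect_false(anyNA(cls$labels))
})

test_that("degenerate and edge class counts behave as specified", {
  expect_error(classify_ndvi(lai_grid(matrix(0.5, 5, 5)), k = 5),
               "distinct valid values")
  g <- lai_grid(matrix(runif(25, 0, 1), 5, 5))
  cls1 <- classify_ndvi(g, k = 1)
  expect_true(all(cls1$labels == 1L))
})

test_that("quantile and kmeans modes give ordered exhaustive classes", {
  withr::with_seed(61, v <- matrix(rnorm(400, 0.5, 0.15), 20, 20))
  v <- pmin(pmax(v, -1), 1)
  g <- lai_grid(v, range = c(-1, 1))
  for (m in c("quantile", "kmeans")) {
    cls <- classify_ndvi(g, k = 4, method = m)
    expect_true(all(diff(cls$class_bounds) > 0), label = m)
    expect_equal(sum(cls$class_counts), 400)
    expect_true(all(diff(cls$class_means) > 0), label = m)
    # ordered: every cell of class i is below every cell of class i+1
    for (i in 1:3)
      expect_lt(max(v[cls$labels == i]), min(v[cls$labels == i + 1]))
  }
  # quantile classes are near-balanced
  clsq <- classify_ndvi(g, k = 4, method = "quantile")
  expect_true(all(abs(clsq$class_counts - 100) <= 2))
})

test_that("no-data cells stay unclassified", {
  v <- matrix(seq(0, 1, length.out = 25), 5, 5)
  v[2, 3] <- NA
  cls <- classify_ndvi(lai_grid(v), k = 3)
  expect_true(is.na(cls$labels[2, 3]))
  expect_equal(sum(cls$class_counts), 24)
})

test_that("calibration recovers an exact line and the two-point case", {
  ndvi <- c(0.2, 0.4, 0.6, 0.8)
  fit <- fit_calibration(ndvi, 2 * ndvi)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1)
  expect_equal(unname(coef(fit)), c(0, 2), tolerance = 1e-12)
  expect_equal(predict(fit, 0.5), 1)

  two <- fit_calibration(c(0.3, 0.7), c(1, 2))
  expect_equal(two$r2, 1)
  expect_equal(predict(two, 0.3), 1)
  expect_equal(predict(two, 0.7), 2)

  expect_error(fit_calibration(c(0.5, 0.5), c(1, 2)), "constant")
  expect_error(fit_calibration(0.5, 1), ">= 2")
})

test_that("calibration recovers a known line from noisy points within 3 SE", {
  a <- 3.2; b <- -0.4
  withr::with_seed(62, {
    ndvi <- runif(5, 0.3, 0.9)
    laiv <- a * ndvi + b + rnorm(5, sd = 0.05)
  })
  fit <- fit_calibration(ndvi, laiv)
  se <- summary(fit$fit)$coefficients[, "Std. Error"]
  expect_lt(abs(fit$slope - a), 3 * se["ndvi"])
  expect_lt(abs(fit$intercept - b), 3 * se["(Intercept)"])
})

test_that("reclassification is the cell-wise linear map with flooring", {
  fit <- fit_calibration(c(0, 1), c(0, 2))        # lai = 2 * ndvi
  v <- matrix(c(0.4, -0.5, NA, 0.1), 2, 2)
  expect_warning(lai <- reclassify_to_lai(lai_grid(v, range = c(-1, 1)), fit),
                 "floored")
  expect_equal(lai$grid[1, 1], 0.8)
  expect_equal(lai$grid[2, 1], 0)                 # floored
  expect_true(is.na(lai$grid[1, 2]))              # no-data preserved
  expect_equal(attr(lai, "n_floored"), 1L)
})

test_that("reclassification is monotone and consistent with class means", {
  withr::with_seed(63, v <- matrix(runif(100, 0.1, 0.9), 10, 10))
  g <- lai_grid(v, range = c(-1, 1))
  fit <- fit_calibration(c(0.1, 0.9), c(0.5, 3))  # positive slope, no flooring
  lai <- reclassify_to_lai(g, fit)
  ord <- order(v)
  expect_true(all(diff(lai$grid[ord]) >= 0))
  cls <- classify_ndvi(g, k = 4)
  for (i in 1:4)
    expect_equal(mean(lai$grid[cls$labels == i]),
                 fit$slope * cls$class_means[i] + fit$intercept,
                 tolerance = 1e-12)
})

test_that("ESRI ASCII grids round trip bit-faithfully", {
  withr::with_seed(64, v <- matrix(runif(48, -1, 1), 6, 8))
  v[3, 4] <- NA
  g <- lai_grid(v, cellsize = 2.5, xll = 100.25, yll = -7.5)
  f <- withr::local_tempfile(fileext = ".asc")
  write_asc_grid(g, f)
  back <- read_asc_grid(f)
  expect_equal(back$grid, g$grid)
  expect_equal(back$cellsize, 2.5)
  expect_equal(back$xll, 100.25)
  expect_equal(back$yll, -7.5)
  expect_error(read_asc_grid("nope.asc"), "not found")
})
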