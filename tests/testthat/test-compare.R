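study <- rect_poly(0, 0, 1000, 1000)

test_that("sample points are reproducible and correctly labelled", {
  imp <- list(rect_poly(0, 0, 200, 1000))  # left 20% of the square
  p1 <- sample_points(study, imp, n = 100, seed = 3)
  p2 <- sample_points(study, imp, n = 100, seed = 3)
  expect_identical(p1, p2)
  expect_true(all(points_in_polygons(p1$x, p1$y, list(study))))

  all_in <- sample_points(study, list(study), n = 50, seed = 1)
  expect_true(all(all_in$group == "mining_impact"))

  # impact fraction approximates the impact-area fraction
  big <- sample_points(study, imp, n = 4000, seed = 9)
  expect_lt(abs(mean(big$group == "mining_impact") - 0.2), 0.03)

  expect_error(sample_points(cbind(c(0, 0), c(0, 0)), imp, n = 5), "empty")
})

test_that("buffer extraction averages the pixels inside the disc", {
  g <- grid_raster(matrix(7.5, 20, 20), cellsize = 50, nodata = NA)  # 1 km sq
  pts <- tibble::tibble(id = 1:2, x = c(500, 100), y = c(500, 900),
                        group = "control")
  ex <- buffer_extract(g, pts, radius = 300)
  expect_true(all(ex$mean == 7.5))
  expect_true(all(ex$n_pixels > 0))

  # half-plane raster: mean at the boundary matches a pixel-loop oracle
  v <- matrix(rep(c(rep(1, 10), rep(3, 10)), 20), 20, 20, byrow = TRUE)
  gh <- grid_raster(v, cellsize = 50, nodata = NA)
  pt <- tibble::tibble(id = 1, x = 500, y = 500, group = "control")
  exh <- buffer_extract(gh, pt, radius = 200)
  cc <- cell_centers(gh)
  inside <- (cc$x - 500)^2 + (cc$y - 500)^2 <= 200^2
  expect_equal(exh$mean, mean(v[inside]))
  expect_gt(exh$mean, 1); expect_lt(exh$mean, 3)

  # all-no-data disc is flagged missing, not zero
  gna <- grid_raster(matrix(NA_real_, 20, 20), cellsize = 50, nodata = NA)
  exna <- buffer_extract(gna, pt, radius = 200)
  expect_true(is.na(exna$mean))
  expect_equal(exna$n_pixels, 0L)
})

test_that("grid aggregation conserves totals", {
  set.seed(13)
  v <- matrix(runif(400), 20, 20)
  g <- grid_raster(v, cellsize = 50, nodata = NA)
  agg <- grid_aggregate(g, cell_size = 250)
  expect_equal(sum(agg$table$total), sum(v))

  uni <- grid_aggregate(grid_raster(matrix(2, 20, 20), cellsize = 50,
                                    nodata = NA), cell_size = 500)
  expect_true(all(uni$table$mean == 2))

  # toy 4-cell case against hand aggregation
  v4 <- matrix(1:16, 4, 4)
  a4 <- grid_aggregate(grid_raster(v4, cellsize = 50, nodata = NA),
                       cell_size = 100)
  hand <- c(sum(v4[3:4, 1:2]), sum(v4[3:4, 3:4]),   # lower-left, lower-right
            sum(v4[1:2, 1:2]), sum(v4[1:2, 3:4]))   # upper-left, upper-right
  expect_equal(a4$table$total, hand)
  expect_error(grid_aggregate(g, cell_size = 10), "at least the pixel")
})

test_that("Mann-Whitney U follows rank-sum definition and symmetry", {
  mt <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mt$U, 0)  # complete separation: all 9 pairs favour b
  expect_equal(mt$medians, c(a = 2, b = 5))

  same <- mann_whitney(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_gt(same$p, 0.9)
  expect_false(same$significant)

  set.seed(17)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  ab <- mann_whitney(a, b)
  ba <- mann_whitney(b, a)
  expect_equal(ab$p, ba$p)
  expect_equal(ba$U, length(a) * length(b) - ab$U)
  # U from midranks agrees with the reference rank-sum statistic
  expect_equal(ab$U, unname(wilcox.test(a, b)$statistic))

  expect_equal(mann_whitney(c(a, NA), b)$n_dropped, 1)
  expect_error(mann_whitney(NA_real_, b), "empty")
})

test_that("group comparison wrapper reports both tests", {
  set.seed(23)
  ex <- tibble::tibble(
    group = rep(c("mining_impact", "control"), each = 30),
    mean = c(rnorm(30, 10), rnorm(30, 12)))
  mw <- compare_groups(ex)
  tt <- compare_groups(ex, method = "t_test")
  expect_true(mw$significant && tt$significant)
  expect_equal(mw$n_impact, 30)
  expect_equal(mw$median_control, median(ex$mean[ex$group == "control"]))

  bx <- box_summary(ex$mean)
  expect_equal(bx$iqr, unname(IQR(ex$mean)))
  expect_true(bx$lower_fence < bx$median && bx$median < bx$upper_fence)
})
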