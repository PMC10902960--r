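D_PRINT <- 1919.32  # printed base unit value used for table checks

test_that("unit-value calibration follows the one-seventh convention", {
  expect_equal(round(calibrate_unit_value(4405, 3.05), 2), 1919.32)
  expect_equal(calibrate_unit_value(7, 1), 1)
  expect_equal(calibrate_unit_value(7000, 2.5), 2500)
  expect_error(calibrate_unit_value(0, 1), "positive")
  expect_error(calibrate_unit_value(100, -2), "positive")
})

test_that("value table is weights times the base unit value", {
  vc <- build_value_table(equivalent_weights(), D_PRINT)
  expect_equal(vc["Woodland", "GR"], 4510.402)
  expect_equal(vc["Grassland", "WS"], 153.5456)
  expect_equal(unclass(vc), equivalent_weights() * D_PRINT,
               ignore_attr = TRUE)
  expect_equal(vc["UnusedLand", "GR"], 0)  # zero weight, zero value

  w <- equivalent_weights()
  w["Cropland", "WT"] <- NA
  expect_error(build_value_table(w, D_PRINT), "Cropland.*WT")
  expect_error(build_value_table(equivalent_weights(), 0), "positive")
})

test_that("static totals aggregate consistently and linearly", {
  vc <- build_value_table(equivalent_weights(), D_PRINT)
  acc <- esv_totals(c(Woodland = 1), vc)
  expect_equal(acc$static, 37177.2284, tolerance = 1e-10)

  zero <- esv_totals(c(Woodland = 0), vc)
  expect_equal(zero$static, 0)
  expect_equal(sum(zero$by_service), 0)

  set.seed(31)
  for (rep in 1:20) {
    a <- setNames(runif(7, 0, 5000), land_use_legend()$class)
    acc <- esv_totals(a, vc)
    expect_equal(sum(acc$by_service), acc$static)
    expect_equal(sum(acc$by_class), acc$static)
    expect_equal(esv_totals(2 * a, vc)$static, 2 * acc$static)
  }
  expect_error(esv_totals(c(Woodland = -1), vc), "non-negative")
})

test_that("deflation reproduces the cumulative-product definition", {
  base <- tibble::tibble(year = 1990:1992, gdp = c(100, 110, 121),
                         gdp_index = c(1, 1.1, 1.1), engel = 0.4,
                         grain_yield = 4405, grain_price = 3.05)
  # identity when all indices are 1
  flat <- base; flat$gdp_index <- 1
  expect_equal(deflate_series(flat, 1990)$series$e_an, flat$gdp)
  # single-step deflation
  d <- deflate_series(base, 1990)
  expect_equal(d$series$e_an[2], 100)
  # explicit cumulative-product oracle over the chain
  e_oracle <- sapply(1:3, function(m) {
    prod_idx <- 1
    for (i in seq_len(m)[-1]) prod_idx <- prod_idx * base$gdp_index[i]
    base$gdp[m] / prod_idx
  })
  expect_equal(d$series$e_an, e_oracle)
  expect_equal(d$e_avg, mean(e_oracle))
  expect_error(deflate_series(base, 1991), "backward")
})

test_that("comparable ESV scales with the deflated economic level", {
  expect_equal(comparable_esv(123, 50, 50), 123)   # E_an = E_avg
  expect_equal(comparable_esv(100, 50, 25), 50)
  expect_equal(comparable_esv(100, 50, 75), 3 * comparable_esv(100, 50, 25))
  expect_error(comparable_esv(100, 0, 10), "positive")
})

test_that("logistic adjustment matches closed-form values and is monotone", {
  d <- dynamic_adjust(100, 1 / 3)
  expect_equal(d$t, 0)
  expect_equal(d$ac, 0.5)
  expect_equal(d$esv_dynamic, 50)
  expect_equal(dynamic_adjust(1, 0.25)$ac, 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(dynamic_adjust(1, 0.25)$ac, 0.731059, tolerance = 1e-6)
  expect_equal(dynamic_adjust(1, 0.1)$ac, 0.999089, tolerance = 1e-6)
  expect_error(dynamic_adjust(1, 0), "\\(0, 1\\]")
  expect_error(dynamic_adjust(1, 1.2), "\\(0, 1\\]")

  # 0.04 floor keeps exp(-t) above double precision so strictness is testable
  en <- seq(0.04, 1, by = 0.02)
  ac <- dynamic_adjust(1, en)$ac
  expect_true(all(diff(ac) < 0))        # strictly decreasing in Engel
  expect_true(all(ac > 0 & ac < 1))
})

test_that("per-pixel ESV raster carries class row sums and no-data", {
  vc <- build_value_table(equivalent_weights(), D_PRINT)
  wood <- uniform_grid(1L, 3, 3)
  r <- esv_value_raster(wood, vc)
  expect_true(all(r$values == 37177.2284))

  built <- uniform_grid(7L, 2, 2)
  rb <- esv_value_raster(built, vc)
  expect_true(all(rb$values < 0))
  expect_equal(rb$values[1], -12.37 * D_PRINT)

  v <- matrix(c(1L, 255L, 2L, 3L), 2, 2)
  rh <- esv_value_raster(grid_raster(v, cellsize = 200), vc)
  expect_true(is.na(rh$values[v == 255]))
  # per-pixel scales by pixel area (200 m -> 4 ha)
  rp <- esv_value_raster(grid_raster(v, cellsize = 200), vc, per = "pixel")
  expect_equal(rp$values[1, 1], 4 * rh$values[1, 1])
})

test_that("esv_accounts runs the full chain per year", {
  s <- constant_series(matrix(2L, 4, 4), 1990:1995)  # static grassland
  socio <- generate_socioeconomic_series(1990:1995, gdp_noise_sd = 0,
                                         engel_start = 0.5, engel_end = 0.4)
  acc <- esv_accounts(s, socio)
  expect_equal(nrow(acc), 6)
  # constant landscape + exact index deflation => static == comparable
  expect_equal(acc$esv_comparable, acc$esv_static, tolerance = 1e-10)
  # dynamic strictly increasing as Engel falls
  expect_true(all(diff(acc$esv_dynamic) > 0))
})
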