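small_cfg <- function(expansion_ha = 125, seed = 5, ...) {
  landscape_config(nrow = 40, ncol = 40, cellsize = 250, n_nuclei = 30,
                   years = 1995:2010, mining_start = 2000,
                   expansion_ha = expansion_ha, restoration_start = NA,
                   noise_rate = 0, seed = seed, ...)
}

test_that("static configuration yields identical rasters every year", {
  cfg <- small_cfg(expansion_ha = 0)
  w <- generate_landscape_series(cfg)
  first <- w$series$rasters[[1]]$values
  for (g in w$series$rasters) expect_identical(g$values, first)
  expect_true(all(w$mined_area_ha == 0))
})

test_that("mined area follows the expansion bookkeeping identity", {
  cfg <- small_cfg()   # 125 ha/yr = 20 px/yr exactly, no restoration
  w <- generate_landscape_series(cfg)
  cap <- sum(polygon_mask(w$series$rasters[[1]], w$concessions)) *
    w$series$pixel_area_ha
  expected <- pmin(cfg$expansion_ha * pmax(cfg$years - cfg$mining_start, 0),
                   cap)
  expect_equal(unname(w$mined_area_ha), expected)

  # class areas are reconstructible from the generator's bookkeeping log
  for (yr in c(1995, 2005, 2010)) {
    areas <- tabulate_areas(w$series, yr)
    logged <- w$class_log[w$class_log$year == yr, ]
    expect_equal(areas$area_ha,
                 logged$pixels[match(areas$class, logged$class)] *
                   w$series$pixel_area_ha)
  }

  # demand beyond the concession area is capped with a warning
  expect_warning(generate_landscape_series(small_cfg(expansion_ha = 5000)),
                 "capped")
})

test_that("the landscape generator is seed-deterministic", {
  w1 <- generate_landscape_series(small_cfg())
  w2 <- generate_landscape_series(small_cfg())
  expect_identical(w1$series$rasters[["2010"]]$values,
                   w2$series$rasters[["2010"]]$values)
  w3 <- generate_landscape_series(small_cfg(seed = 6))
  expect_false(identical(w1$series$rasters[["1995"]]$values,
                         w3$series$rasters[["1995"]]$values))
})

test_that("socioeconomic generator honours growth and telescoping", {
  flat <- generate_socioeconomic_series(1990:2000, gdp_growth = 0,
                                        gdp_noise_sd = 0)
  expect_true(all(flat$gdp == flat$gdp[1]))
  expect_true(all(flat$gdp_index == 1))

  g5 <- generate_socioeconomic_series(1990:2000, gdp_growth = 0.05,
                                      gdp_noise_sd = 0)
  expect_equal(g5$gdp_index[-1], rep(1.05, 10))

  noisy <- generate_socioeconomic_series(1990:2020, gdp_noise_sd = 0.05,
                                         seed = 2)
  expect_equal(prod(noisy$gdp_index[-1]),
               noisy$gdp[31] / noisy$gdp[1], tolerance = 1e-12)
  expect_error(generate_socioeconomic_series(1990:2000, engel_start = 0),
               "\\(0, 1\\]")
})

test_that("piecewise generator round-trips through the joinpoint fit", {
  t <- 1990:2020
  const <- generate_piecewise_series(t, numeric(0), 0)
  expect_equal(const$value, rep(100, length(t)))

  s <- generate_piecewise_series(t, c(1999, 2008), c(2, -1, 0.5))
  f <- fit_segments(t, s$value, breakpoints = c(1999, 2008))
  expect_equal(apc(f)$apc, c(2, -1, 0.5), tolerance = 1e-9)

  ctrl <- generate_piecewise_series(t, c(1997, 2005, 2009),
                                    c(1.09, 0.43, 1.01, 0.51))
  fc <- fit_segments(t, ctrl$value, breakpoints = c(1997, 2005, 2009))
  expect_equal(round(aapc(fc)$aapc, 1), 0.7)

  expect_error(generate_piecewise_series(t, 1990, c(1, 2)), "inside")
  expect_error(generate_piecewise_series(t, 2000, 1), "one APC per segment")
})

test_that("mining depresses concession ESV relative to the control area", {
  w <- generate_landscape_series()   # default scenario
  socio <- generate_socioeconomic_series(w$series$years)
  total <- esv_accounts(w$series, socio)
  mining <- esv_accounts(w$series, socio, mask = w$concessions)
  control <- total$esv_dynamic - mining$esv_dynamic
  # concession dynamic ESV ends below its pre-mining peak; control does not
  expect_lt(mining$esv_dynamic[length(w$series$years)],
            max(mining$esv_dynamic))
  expect_equal(which.max(control), length(control))
})
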