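test_that("segment fitting recovers exact log-linear structure", {
  t <- 1990:2010
  y <- exp(0.01 * t)
  f <- fit_segments(t, y)
  expect_equal(unname(f$slopes), 0.01, tolerance = 1e-12)
  expect_length(f$breakpoints, 0)

  # zero breakpoints is ordinary log-linear regression
  set.seed(2)
  y_noisy <- y * exp(rnorm(length(t), 0, 0.01))
  lmfit <- lm(log(y_noisy) ~ t)
  f0 <- fit_segments(t, y_noisy, numeric(0))
  expect_equal(unname(f0$slopes), unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(unname(f0$slope_se), unname(sqrt(vcov(lmfit)[2, 2])),
               tolerance = 1e-8)

  # noiseless two-piece log-line, breakpoint given: both slopes recovered
  brk <- 2000
  logy <- 3 + 0.02 * (t - 1990) - 0.05 * pmax(t - brk, 0)
  f2 <- fit_segments(t, exp(logy), breakpoints = brk)
  expect_equal(unname(f2$slopes), c(0.02, -0.03), tolerance = 1e-10)

  expect_error(fit_segments(t, c(-1, y[-1])), "positive series")
  expect_error(fit_segments(t, y, breakpoints = 2009.5), "degenerate segment")
  expect_error(fit_segments(t, y, breakpoints = 1990), "strictly inside")
})

test_that("fitted log-curve is continuous at every breakpoint", {
  t <- 1990:2020
  s <- generate_piecewise_series(t, c(1999, 2010), c(2, -1, 0.5),
                                 log_noise_sd = 0.05, seed = 3)
  f <- fit_segments(t, s$value, breakpoints = c(1999, 2010))
  co <- f$coefficients
  curve <- function(x) co[1] + co[2] * x + co[3] * pmax(x - 1999, 0) +
    co[4] * pmax(x - 2010, 0)
  for (b in f$breakpoints) {
    h <- 1e-8
    expect_equal(curve(b - h), curve(b + h), tolerance = 1e-6)
  }
})

test_that("joinpoint results are invariant to time shifts and value scaling", {
  t <- 1990:2020
  s <- generate_piecewise_series(t, 2004, c(1.5, -0.8), log_noise_sd = 0.02,
                                 seed = 9)
  f <- fit_segments(t, s$value, breakpoints = 2004)
  f_shift <- fit_segments(t - 1990, s$value, breakpoints = 14)
  expect_equal(f_shift$slopes, f$slopes, tolerance = 1e-9)
  expect_equal(apc(f_shift)$apc, apc(f)$apc, tolerance = 1e-9)
  expect_equal(aapc(f_shift)$aapc, aapc(f)$aapc, tolerance = 1e-9)

  f_scale <- fit_segments(t, 1000 * s$value, breakpoints = 2004)
  expect_equal(f_scale$slopes, f$slopes, tolerance = 1e-9)
  expect_equal(f_scale$coefficients[1] - f$coefficients[1], log(1000),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("model selection finds the true number of joinpoints", {
  t <- 1990:2020
  # noiseless single log-line: k = 0
  f0 <- select_model(t, exp(0.02 * (t - 1990) + 1), max_joinpoints = 3)
  expect_length(f0$breakpoints, 0)

  # one strong kink at year 16 (2005), small noise: k = 1 within +-1 year
  s1 <- generate_piecewise_series(t, 2005, c(2, -1.5), log_noise_sd = 0.01,
                                  seed = 21)
  f1 <- select_model(t, s1$value, max_joinpoints = 3)
  expect_length(f1$breakpoints, 1)
  expect_lte(abs(f1$breakpoints - 2005), 1)

  # two well-separated kinks, low noise: k = 2, both within +-1 year
  s2 <- generate_piecewise_series(t, c(1998, 2010), c(2.5, -1.5, 1),
                                  log_noise_sd = 0.01, seed = 22)
  f2 <- select_model(t, s2$value, max_joinpoints = 3)
  expect_length(f2$breakpoints, 2)
  expect_true(all(abs(f2$breakpoints - c(1998, 2010)) <= 1))

  expect_error(select_model(2000:2005, exp(rnorm(6) + 5), max_joinpoints = 3),
               "at most")
})

test_that("APC converts segment slopes to percent change", {
  t <- 1990:2020
  s <- generate_piecewise_series(t, 2005, c(0, 0), log_noise_sd = 0.001,
                                 seed = 4)
  f <- fit_segments(t, s$value, breakpoints = 2005)
  a <- apc(f)
  expect_equal(a$apc, c(0, 0), tolerance = 0.1)
  expect_equal(nrow(a), 2)
  expect_equal(a$start, c(1990, 2005))
  expect_equal(a$end, c(2005, 2020))

  # closed-form conversions
  expect_equal((exp(log(1.0109)) - 1) * 100, 1.09)
  noiseless <- generate_piecewise_series(t, numeric(0), 1.09)
  fb <- fit_segments(t, noiseless$value)
  expect_equal(apc(fb)$apc, 1.09, tolerance = 1e-9)
  down <- generate_piecewise_series(t, numeric(0), -0.67)
  expect_equal(apc(fit_segments(t, down$value))$apc, -0.67, tolerance = 1e-9)
})

test_that("AAPC weights segment slopes by their spans", {
  # single segment: AAPC = APC
  expect_equal(aapc(2.4, weights = 31)$aapc, 2.4)
  # reported-value path: control and mining scenarios
  expect_equal(round(aapc(c(1.09, 0.43, 1.01, 0.51),
                          weights = c(7, 8, 4, 11))$aapc, 1), 0.7)
  expect_equal(round(aapc(c(0.00, 0.78, 0.09, -0.67),
                          weights = c(6, 3, 8, 13))$aapc, 1), -0.2)
  expect_error(aapc(c(1, 2), weights = 1), "equal length")
  expect_error(aapc(-100, weights = 5), "-100")

  # fit path agrees with the reported-value path on the point estimate
  t <- 1990:2020
  s <- generate_piecewise_series(t, c(1997, 2005, 2009),
                                 c(1.09, 0.43, 1.01, 0.51))
  f <- fit_segments(t, s$value, breakpoints = c(1997, 2005, 2009))
  expect_equal(aapc(f)$aapc,
               aapc(apc(f)$apc, weights = diff(c(1990, 1997, 2005, 2009,
                                                 2020)))$aapc,
               tolerance = 1e-9)
  expect_equal(round(aapc(f)$aapc, 1), 0.7)
  # delta-method CI is a proper interval around the estimate
  aa <- aapc(f)
  expect_true(aa$lo <= aa$aapc && aa$aapc <= aa$hi)
})
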