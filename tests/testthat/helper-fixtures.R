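# shared fixtures: tiny rasters and series built in code

# uniform categorical grid; cellsize 100 m -> exactly 1 ha per pixel
uniform_grid <- function(code, nr = 2, nc = 2, cellsize = 100) {
  grid_raster(matrix(as.integer(code), nr, nc), cellsize = cellsize)
}

# one-raster-per-year series where every year shares one matrix
constant_series <- function(values, years, cellsize = 100) {
  land_use_series(lapply(years, function(y)
    grid_raster(values, cellsize = cellsize)), years)
}

# rectangle polygon in map units
rect_poly <- function(x0, y0, x1, y1) {
  cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
}

# independent brute-force oracles -------------------------------------------

sen_oracle <- function(values, times = seq_along(values)) {
  sl <- c()
  n <- length(values)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      sl <- c(sl, (values[j] - values[i]) / (times[j] - times[i]))
  median(sl)
}

mk_oracle <- function(values) {
  n <- length(values)
  S <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      S <- S + sign(values[j] - values[i])
  varS <- n * (n - 1) * (2 * n + 5) / 18
  Z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS)
       else 0
  list(S = S, varS = varS, Z = Z)
}
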