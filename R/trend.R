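#' Theil-Sen slope
#'
#' Robust trend magnitude: the median of all `n(n-1)/2` pairwise slopes
#' `(v_j - v_i) / (t_j - t_i)`, `j > i`. Insensitive to outliers and to the
#' distribution of the values.
#'
#' @param values Numeric series.
#' @param times Observation times (strictly increasing); defaults to
#'   `1..n`.
#' @return The Sen slope (value per time unit).
#' @export
#' @examples
#' sen_slope(c(1, 2, 10), 0:2)  # median of {1, 4.5, 8} = 4.5
sen_slope <- function(values, times = seq_along(values)) {
  n <- length(values)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  ij <- utils::combn(n, 2)
  stats::median((values[ij[2, ]] - values[ij[1, ]]) /
                (times[ij[2, ]] - times[ij[1, ]]))
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test. `S` counts concordant minus
#' discordant pairs, `Var(S) = n(n-1)(2n+5)/18` (optionally tie-corrected),
#' and the standardised statistic uses the continuity correction
#' `Z = (S-1)/sqrt(Var)` for `S > 0`, `0` for `S = 0`, and
#' `(S+1)/sqrt(Var)` for `S < 0`.
#'
#' @param values Numeric series.
#' @param tie_correction Subtract the tie term
#'   `sum t(t-1)(2t+5)/18` from `Var(S)`? Off by default (the plain
#'   formula is the reference behaviour).
#' @param min_n Minimum series length for the normal approximation.
#' @return List with `S`, `varS`, `Z`.
#' @export
#' @examples
#' mk_test(1:5)  # S = 10, varS = 16.67, Z = 2.20
mk_test <- function(values, tie_correction = FALSE, min_n = 4) {
  n <- length(values)
  if (n < min_n)
    stop("series shorter than the minimum of ", min_n, " observations",
         call. = FALSE)
  ij <- utils::combn(n, 2)
  S <- sum(sign(values[ij[2, ]] - values[ij[1, ]]))
  varS <- n * (n - 1) * (2 * n + 5) / 18
  if (tie_correction) {
    tt <- table(values)
    tt <- tt[tt > 1]
    varS <- varS - sum(tt * (tt - 1) * (2 * tt + 5)) / 18
  }
  Z <- if (S > 0) (S - 1) / sqrt(varS) else if (S < 0) (S + 1) / sqrt(varS)
       else 0
  list(S = S, varS = varS, Z = Z)
}

#' Five-way trend classification
#'
#' Combines the Sen slope (direction and magnitude) with the Mann-Kendall
#' `Z` (significance): slopes within `beta_threshold` of zero are
#' "NoTrend"; otherwise the sign of the slope gives the direction and
#' `|Z| >= z_threshold` upgrades it from slight to significant. The default
#' `z_threshold = 2.58` corresponds to the 0.01 two-sided level.
#'
#' @param beta Sen slope(s).
#' @param z Mann-Kendall Z statistic(s).
#' @param beta_threshold Slope magnitude below which there is no trend.
#' @param z_threshold Significance cut on `|Z|`.
#' @return Character vector of [trend_classes()] labels.
#' @export
classify_trend <- function(beta, z, beta_threshold = 0.005,
                           z_threshold = 2.58) {
  if (beta_threshold <= 0 || z_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  out <- rep(NA_character_, length(beta))
  sig <- abs(z) >= z_threshold
  out[abs(beta) < beta_threshold] <- "NoTrend"
  out[beta >= beta_threshold & sig]  <- "SignificantIncrease"
  out[beta >= beta_threshold & !sig] <- "SlightIncrease"
  out[beta <= -beta_threshold & sig]  <- "SignificantDecrease"
  out[beta <= -beta_threshold & !sig] <- "SlightDecrease"
  out
}

#' Per-pixel trend analysis of a raster stack
#'
#' Applies [sen_slope()], [mk_test()] and [classify_trend()] to every pixel
#' of an annual value stack. A pixel with a no-data value in any year is
#' no-data in all outputs (set `pairwise_complete = TRUE` to use, per
#' pixel, only the years with data).
#'
#' @param stack List of continuous [grid_raster()] on a shared grid, one
#'   per year.
#' @param years Observation years (strictly increasing).
#' @param beta_threshold,z_threshold Classification thresholds, see
#'   [classify_trend()].
#' @param pairwise_complete Keep pixels with missing years, using the
#'   available pairs only?
#' @return List of three [grid_raster()]: `beta`, `z` and `class` (integer
#'   codes 1..5 in [trend_classes()] order).
#' @export
trend_raster <- function(stack, years, beta_threshold = 0.005,
                         z_threshold = 2.58, pairwise_complete = FALSE) {
  n <- length(stack)
  if (n < 4) stop("need at least four years", call. = FALSE)
  if (length(years) != n || is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing, one per raster", call. = FALSE)
  g1 <- stack[[1]]
  for (g in stack[-1])
    if (!same_grid(g1, g)) stop("mismatched raster grids", call. = FALSE)
  npx <- length(g1$values)
  V <- vapply(stack, function(g) {
    v <- g$values
    v[!valid_mask(g)] <- NA
    as.vector(v)
  }, numeric(npx))                               # pixels x years
  complete <- rowSums(is.na(V)) == 0
  use <- if (pairwise_complete) rowSums(!is.na(V)) >= 4 else complete

  ij <- utils::combn(n, 2)
  npair <- ncol(ij)
  slopes <- matrix(NA_real_, sum(use), npair)
  S <- numeric(sum(use))
  nobs <- rowSums(!is.na(V[use, , drop = FALSE]))
  Vu <- V[use, , drop = FALSE]
  for (p in seq_len(npair)) {
    d <- Vu[, ij[2, p]] - Vu[, ij[1, p]]
    slopes[, p] <- d / (years[ij[2, p]] - years[ij[1, p]])
    S <- S + ifelse(is.na(d), 0, sign(d))
  }
  beta <- apply(slopes, 1, stats::median, na.rm = TRUE)
  varS <- nobs * (nobs - 1) * (2 * nobs + 5) / 18
  z <- ifelse(S > 0, (S - 1) / sqrt(varS),
       ifelse(S < 0, (S + 1) / sqrt(varS), 0))
  cls <- match(classify_trend(beta, z, beta_threshold, z_threshold),
               trend_classes())

  mk_grid <- function(vals) {
    full <- rep(NA_real_, npx)
    full[use] <- vals
    grid_raster(matrix(full, nrow(g1$values), ncol(g1$values)),
                g1$xmin, g1$ymin, g1$cellsize, nodata = NA)
  }
  list(beta = mk_grid(beta), z = mk_grid(z), class = mk_grid(cls))
}

#' Summarise a trend-class raster
#'
#' Per-class areas (km^2) and percentages over valid pixels.
#'
#' @param class_grid Class [grid_raster()] from [trend_raster()] (codes
#'   1..5 in [trend_classes()] order).
#' @param pixel_area Pixel area in hectares; derived from the grid by
#'   default.
#' @return Tibble with `class`, `area_km2`, `percent`. See
#'   [trend_aggregates()] for the improved/degraded rollup.
#' @export
summarize_classes <- function(class_grid, pixel_area = pixel_area_ha(class_grid)) {
  v <- class_grid$values[valid_mask(class_grid)]
  if (!length(v)) stop("class raster has no valid pixels", call. = FALSE)
  counts <- tabulate(factor(v, levels = 1:5), nbins = 5)
  tibble::tibble(class = trend_classes(),
                 area_km2 = counts * pixel_area / 100,
                 percent = 100 * counts / length(v))
}

#' Improved / degraded aggregates of trend-class shares
#'
#' Improved = slight + significant increase; degraded = slight +
#' significant decrease.
#'
#' @param percent Percentages (or areas) named by [trend_classes()] labels,
#'   or the summary tibble from [summarize_classes()].
#' @return Named numeric vector `c(improved =, degraded =, stable =)`.
#' @export
#' @examples
#' trend_aggregates(c(SignificantIncrease = 41.15, SlightIncrease = 7.30,
#'                    NoTrend = 30.27, SlightDecrease = 4.09,
#'                    SignificantDecrease = 17.19))
trend_aggregates <- function(percent) {
  if (is.data.frame(percent))
    percent <- stats::setNames(percent$percent, percent$class)
  p <- stats::setNames(rep(0, 5), trend_classes())
  p[names(percent)] <- percent
  c(improved = unname(p["SignificantIncrease"] + p["SlightIncrease"]),
    degraded = unname(p["SignificantDecrease"] + p["SlightDecrease"]),
    stable = unname(p["NoTrend"]))
}
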