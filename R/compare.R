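#' Random sample points with impact/control labels
#'
#' Draws uniform-random points inside the study polygon (rejection
#' sampling over its bounding box) and labels each point `mining_impact`
#' or `control` by containment in the impact polygons (the mining
#' concessions, optionally dilated by an influence buffer).
#'
#' @param study Study-area polygon (two-column vertex matrix).
#' @param impact List of impact polygons (may be empty).
#' @param n Number of points (default 300).
#' @param seed RNG seed; the point set is fully reproducible.
#' @param influence Dilation of the impact polygons in metres (default 0:
#'   the concession boundary itself delimits the impact area).
#' @return Tibble with `x`, `y`, `group` and `id`; attribute
#'   `buffer_radius` records the default extraction radius.
#' @export
sample_points <- function(study, impact, n = 300, seed = 1, influence = 0) {
  if (n < 1) stop("need at least one point", call. = FALSE)
  study <- close_ring(study)
  if (nrow(study) < 4 || abs(ring_area(study)) == 0)
    stop("study polygon is empty", call. = FALSE)
  if (influence > 0) impact <- lapply(impact, dilate_ring, by = influence)
  bb <- apply(study, 2, range)
  pts <- withr::with_seed(seed, {
    acc <- matrix(numeric(0), 0, 2)
    while (nrow(acc) < n) {
      m <- max(2 * (n - nrow(acc)), 32)
      cand <- cbind(stats::runif(m, bb[1, 1], bb[2, 1]),
                    stats::runif(m, bb[1, 2], bb[2, 2]))
      keep <- mgcv::in.out(study, cand)
      acc <- rbind(acc, cand[keep, , drop = FALSE])
    }
    acc[seq_len(n), , drop = FALSE]
  })
  grp <- ifelse(points_in_polygons(pts[, 1], pts[, 2], impact),
                "mining_impact", "control")
  out <- tibble::tibble(id = seq_len(n), x = pts[, 1], y = pts[, 2],
                        group = grp)
  attr(out, "buffer_radius") <- 1000
  out
}

ring_area <- function(m) {
  m <- close_ring(m)
  x <- m[, 1]; y <- m[, 2]
  sum(x[-nrow(m)] * y[-1] - x[-1] * y[-nrow(m)]) / 2
}

# crude isotropic dilation about the ring centroid; adequate for the
# convex rectangular concessions the generator produces
dilate_ring <- function(m, by) {
  m <- close_ring(m)
  cx <- mean(m[-nrow(m), 1]); cy <- mean(m[-nrow(m), 2])
  d <- sqrt((m[, 1] - cx)^2 + (m[, 2] - cy)^2)
  f <- (d + by) / d
  cbind(cx + (m[, 1] - cx) * f, cy + (m[, 2] - cy) * f)
}

#' Extract buffered means at sample points
#'
#' For each point, averages the raster over all valid pixels whose centres
#' fall within `radius` metres of the point (a disc). Points whose disc
#' contains no valid pixel get `NA` and are reported, not silently
#' dropped; points with incomplete discs at the study edge keep the mean
#' of the valid pixels.
#'
#' @param grid Continuous [grid_raster()] (e.g. ESV per hectare).
#' @param points Tibble from [sample_points()] (columns `x`, `y`).
#' @param radius Buffer radius in metres (default 1000).
#' @return The points tibble plus columns `mean` and `n_pixels`.
#' @export
buffer_extract <- function(grid, points, radius = 1000) {
  cc <- cell_centers(grid)
  keep <- valid_mask(grid)
  px <- as.vector(cc$x)[keep]; py <- as.vector(cc$y)[keep]
  pv <- grid$values[keep]
  r2 <- radius^2
  res <- vapply(seq_len(nrow(points)), function(i) {
    inside <- (px - points$x[i])^2 + (py - points$y[i])^2 <= r2
    k <- sum(inside)
    c(if (k) mean(pv[inside]) else NA_real_, k)
  }, numeric(2))
  out <- points
  out$mean <- res[1, ]
  out$n_pixels <- as.integer(res[2, ])
  out
}

#' Aggregate a raster to a coarse grid
#'
#' Partitions the extent into axis-aligned square cells anchored at the
#' raster origin (its lower-left corner) and reports per-cell means and
#' totals over valid pixels. Cell totals conserve the raster total.
#'
#' @param grid Continuous [grid_raster()].
#' @param cell_size Aggregation cell edge in metres (default 10 km); must
#'   be at least the pixel size.
#' @return List with `table` (tibble: `cell_x`, `cell_y`, `n_pixels`,
#'   `mean`, `total`) and `grid` (a coarse [grid_raster()] of cell means).
#' @export
grid_aggregate <- function(grid, cell_size = 10000) {
  if (cell_size < grid$cellsize)
    stop("cell_size must be at least the pixel size", call. = FALSE)
  cc <- cell_centers(grid)
  keep <- as.vector(valid_mask(grid))
  ix <- floor((as.vector(cc$x) - grid$xmin) / cell_size)
  iy <- floor((as.vector(cc$y) - grid$ymin) / cell_size)
  v <- as.vector(grid$values)
  nx <- max(ix) + 1; ny <- max(iy) + 1
  key <- ix + nx * iy
  tot <- rowsum(ifelse(keep, v, 0), key)
  cnt <- rowsum(as.numeric(keep), key)
  keys <- as.numeric(rownames(tot))
  tot <- unname(tot[, 1]); cnt <- unname(cnt[, 1])
  tab <- tibble::tibble(cell_x = keys %% nx, cell_y = keys %/% nx,
                        n_pixels = as.integer(cnt),
                        mean = ifelse(cnt > 0, tot / cnt, NA),
                        total = ifelse(cnt > 0, tot, NA))
  m <- matrix(NA_real_, ny, nx)
  m[cbind(ny - tab$cell_y, tab$cell_x + 1)] <- tab$mean
  list(table = tab,
       grid = grid_raster(m, grid$xmin, grid$ymin, cell_size, nodata = NA))
}

#' Mann-Whitney U comparison of two groups
#'
#' Rank-sum test of whether two groups (e.g. mining-impact vs control
#' sample points) come from the same distribution. `U` is computed from
#' midrank sums; the two-sided p-value comes from the exact distribution
#' for small tie-free samples and the normal approximation with tie
#' correction otherwise (via [stats::wilcox.test()]). Medians and
#' interquartile ranges are reported per group; missing values are dropped
#' with their count.
#'
#' @param group_a,group_b Numeric samples (missing values allowed).
#' @param alpha Significance level for the `significant` flag.
#' @return List of class `mw_test`: `U` (for `group_a`), `p`,
#'   `significant`, `medians`, `iqrs`, `n`, `n_dropped`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$U  # 0: complete separation
mann_whitney <- function(group_a, group_b, alpha = 0.05) {
  n_dropped <- sum(is.na(group_a)) + sum(is.na(group_b))
  a <- group_a[!is.na(group_a)]
  b <- group_b[!is.na(group_b)]
  if (!length(a) || !length(b))
    stop("a group is empty after dropping missing values", call. = FALSE)
  r <- rank(c(a, b))                       # midranks for ties
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = NULL,
                                            correct = TRUE))
  structure(list(U = U, p = wt$p.value, significant = wt$p.value < alpha,
                 alpha = alpha,
                 medians = c(a = stats::median(a), b = stats::median(b)),
                 iqrs = c(a = stats::IQR(a), b = stats::IQR(b)),
                 n = c(a = length(a), b = length(b)),
                 n_dropped = n_dropped),
            class = "mw_test")
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (%ssignificant at %.2g)\n",
              x$U, x$p, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' Five-number boxplot summary with Tukey fences
#'
#' Median, quartiles, interquartile range and outliers beyond
#' 1.5 x IQR, per group.
#'
#' @param values Numeric vector.
#' @return Tibble with `median`, `q1`, `q3`, `iqr`, `lower_fence`,
#'   `upper_fence`, `n_outliers`, `n`.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lf <- q[1] - 1.5 * iqr
  uf <- q[3] + 1.5 * iqr
  tibble::tibble(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 lower_fence = lf, upper_fence = uf,
                 n_outliers = sum(values < lf | values > uf),
                 n = length(values))
}

#' Compare impact and control groups on extracted values
#'
#' Convenience wrapper: splits a [buffer_extract()] result by group and
#' runs the Mann-Whitney U test (default) or Welch's t-test.
#'
#' @param extracted Tibble with columns `group` and `mean`.
#' @param method `"mann_whitney"` (default) or `"t_test"`.
#' @param alpha Significance level.
#' @return One-row tibble: group medians/IQRs, sample sizes, the test
#'   statistic and p-value.
#' @export
compare_groups <- function(extracted, method = c("mann_whitney", "t_test"),
                           alpha = 0.05) {
  method <- match.arg(method)
  a <- extracted$mean[extracted$group == "mining_impact"]
  b <- extracted$mean[extracted$group == "control"]
  if (method == "mann_whitney") {
    mt <- mann_whitney(a, b, alpha)
    stat <- mt$U; p <- mt$p
  } else {
    tt <- stats::t.test(a, b)
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  tibble::tibble(method = method,
                 n_impact = sum(!is.na(a)), n_control = sum(!is.na(b)),
                 median_impact = stats::median(a, na.rm = TRUE),
                 median_control = stats::median(b, na.rm = TRUE),
                 iqr_impact = stats::IQR(a, na.rm = TRUE),
                 iqr_control = stats::IQR(b, na.rm = TRUE),
                 statistic = stat, p_value = p, significant = p < alpha)
}
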