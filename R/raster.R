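#' Lightweight regular raster grid
#'
#' A minimal single-band raster container used throughout the pipeline:
#' a value matrix on a regular grid in a projected (metric) coordinate
#' system, with a lower-left corner, square cell size in metres and a
#' no-data code. Row 1 of the matrix is the northernmost row, matching the
#' on-disk ESRI ASCII grid layout.
#'
#' @param values Numeric or integer matrix; row 1 = north.
#' @param xmin,ymin Coordinates of the lower-left corner (metres).
#' @param cellsize Cell edge length in metres (square cells).
#' @param nodata No-data code for integer/categorical grids (default 255);
#'   continuous grids use `NA`/`NaN` as well.
#' @return An object of class `grid_raster`.
#' @export
#' @examples
#' g <- grid_raster(matrix(1L, 2, 2), cellsize = 100)
#' pixel_area_ha(g)
grid_raster <- function(values, xmin = 0, ymin = 0, cellsize = 100,
                        nodata = 255) {
  if (!is.matrix(values)) stop("values must be a matrix", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, nodata = nodata),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, %g m, origin (%g, %g), nodata %s\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin,
              format(x$nodata)))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Pixel area in hectares
#'
#' @param grid A [grid_raster()].
#' @return Area of one cell in hectares (cellsize^2 / 1e4).
#' @export
pixel_area_ha <- function(grid) grid$cellsize^2 / 1e4

#' Logical mask of valid (non-no-data) pixels
#' @param grid A [grid_raster()].
#' @return Logical matrix, TRUE where the pixel carries data.
#' @export
valid_mask <- function(grid) {
  ok <- !is.na(grid$values)
  if (!is.na(grid$nodata)) ok <- ok & (grid$values != grid$nodata)
  ok
}

#' Cell-centre coordinates
#'
#' @param grid A [grid_raster()].
#' @return List with matrices `x` and `y` of the same shape as the grid,
#'   holding cell-centre coordinates.
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  cx <- grid$xmin + (seq_len(nc) - 0.5) * grid$cellsize
  cy <- grid$ymin + (nr - seq_len(nr) + 0.5) * grid$cellsize  # row 1 = north
  list(x = matrix(cx, nr, nc, byrow = TRUE),
       y = matrix(cy, nr, nc))
}

same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

#' Write / read an ESRI ASCII grid
#'
#' Plain-text raster interchange. `NA`/`NaN` cells are written as the
#' declared no-data value.
#'
#' @param grid A [grid_raster()].
#' @param path File path (conventionally `.asc`).
#' @param digits Significant digits for continuous grids.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a [grid_raster()].
#' @export
write_ascii_grid <- function(grid, path, digits = 8) {
  v <- grid$values
  nd <- if (is.na(grid$nodata)) -9999 else grid$nodata
  v[is.na(v)] <- nd
  hdr <- sprintf(paste0("ncols %d\nnrows %d\nxllcorner %.10g\n",
                        "yllcorner %.10g\ncellsize %.10g\nNODATA_value %.10g"),
                 ncol(v), nrow(v), grid$xmin, grid$ymin, grid$cellsize, nd)
  body <- apply(signif(v, digits), 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path, n = 6)
  kv <- strsplit(trimws(ln), "\\s+")
  hdr <- stats::setNames(vapply(kv, function(p) as.numeric(p[2]), 0),
                         tolower(vapply(kv, `[`, "", 1)))
  v <- matrix(scan(path, skip = 6, quiet = TRUE),
              nrow = hdr[["nrows"]], ncol = hdr[["ncols"]], byrow = TRUE)
  nd <- hdr[["nodata_value"]]
  v[v == nd] <- NA
  grid_raster(v, xmin = hdr[["xllcorner"]], ymin = hdr[["yllcorner"]],
              cellsize = hdr[["cellsize"]], nodata = NA)
}

#' Simple polygons and GeoJSON I/O
#'
#' Polygons are lists of rings: each polygon is a two-column matrix of
#' (x, y) vertices (closed or open; closure is implied). `write_geojson()`
#' and `read_geojson()` exchange them as a GeoJSON FeatureCollection of
#' single-ring Polygon features with optional properties.
#'
#' @param polys List of two-column vertex matrices.
#' @param path File path.
#' @param properties Optional data frame, one row per polygon.
#' @return `read_geojson()` returns a list with `polygons` and `properties`.
#' @export
write_geojson <- function(polys, path, properties = NULL) {
  feats <- lapply(seq_along(polys), function(i) {
    m <- close_ring(polys[[i]])
    props <- if (is.null(properties)) stats::setNames(list(), character()) else
      as.list(properties[i, , drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(unname(apply(m, 1, c,
                                                         simplify = FALSE)))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  polys <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  })
  props <- lapply(fc$features, function(f) f$properties)
  list(polygons = polys, properties = props)
}

close_ring <- function(m) {
  m <- as.matrix(m)
  if (!isTRUE(all.equal(m[1, ], m[nrow(m), ]))) m <- rbind(m, m[1, ])
  m
}

#' Point-in-polygon test
#'
#' @param x,y Point coordinates.
#' @param polys List of two-column vertex matrices (see [write_geojson()]).
#' @return Logical vector: TRUE where the point falls inside any polygon.
#' @export
points_in_polygons <- function(x, y, polys) {
  if (!length(polys)) return(rep(FALSE, length(x)))
  pts <- cbind(x, y)
  inside <- rep(FALSE, length(x))
  for (p in polys) {
    m <- close_ring(p)
    inside <- inside | mgcv::in.out(m, pts)
  }
  inside
}

#' Rasterise polygons to a logical mask
#'
#' @param grid A [grid_raster()] supplying the geometry.
#' @param polys List of polygons; `NULL` means "everything".
#' @return Logical matrix: TRUE where the cell centre falls inside a polygon.
#' @export
polygon_mask <- function(grid, polys) {
  if (is.null(polys)) return(matrix(TRUE, nrow(grid$values), ncol(grid$values)))
  cc <- cell_centers(grid)
  matrix(points_in_polygons(as.vector(cc$x), as.vector(cc$y), polys),
         nrow(grid$values), ncol(grid$values))
}

#' Annual land-use raster series
#'
#' Bundles one categorical raster per year on a shared grid together with
#' the legend and derived pixel area.
#'
#' @param rasters Named or unnamed list of [grid_raster()], one per year.
#' @param years Integer years, strictly increasing, same length as `rasters`.
#' @param legend Legend tibble as from [land_use_legend()].
#' @return An object of class `land_use_series`.
#' @export
land_use_series <- function(rasters, years, legend = land_use_legend()) {
  if (length(rasters) != length(years))
    stop("need exactly one raster per year", call. = FALSE)
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing", call. = FALSE)
  for (r in rasters[-1])
    if (!same_grid(rasters[[1]], r))
      stop("all rasters must share extent, resolution and shape",
           call. = FALSE)
  bad <- setdiff(unique(as.vector(rasters[[1]]$values)),
                 c(legend$code, rasters[[1]]$nodata, NA))
  if (length(bad))
    stop("raster values outside legend: ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(rasters = stats::setNames(rasters, years), years = years,
                 legend = legend, pixel_area_ha = pixel_area_ha(rasters[[1]])),
            class = "land_use_series")
}

#' @export
print.land_use_series <- function(x, ...) {
  cat(sprintf("<land_use_series> %d years (%d-%d), %d x %d cells, %.4g ha/px\n",
              length(x$years), min(x$years), max(x$years),
              nrow(x$rasters[[1]]$values), ncol(x$rasters[[1]]$values),
              x$pixel_area_ha))
  invisible(x)
}

#' Tabulate per-class areas for one year
#'
#' Counts valid pixels per land-use class (optionally restricted to a
#' polygon mask) and converts to hectares.
#'
#' @param series A [land_use_series()].
#' @param year The year to tabulate; must be present in the series.
#' @param mask Optional list of polygons restricting the tabulation.
#' @return Tibble with columns `class`, `code`, `area_ha`; attribute
#'   `valid_pixels` carries the count of contributing pixels. A disjoint
#'   mask or an all-no-data raster yields zero areas with a warning.
#' @export
tabulate_areas <- function(series, year, mask = NULL) {
  if (!year %in% series$years)
    stop("year ", year, " not present in the series", call. = FALSE)
  g <- series$rasters[[as.character(year)]]
  keep <- valid_mask(g) & polygon_mask(g, mask)
  n_valid <- sum(keep)
  if (n_valid == 0)
    warning(if (is.null(mask)) "raster has no valid pixels"
            else "mask selects no valid pixels; areas are all zero",
            call. = FALSE)
  counts <- tabulate(factor(g$values[keep], levels = series$legend$code),
                     nbins = nrow(series$legend))
  out <- tibble::tibble(class = series$legend$class,
                        code = series$legend$code,
                        area_ha = counts * series$pixel_area_ha)
  attr(out, "valid_pixels") <- n_valid
  out
}
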