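#' Calibrate the base unit value from grain statistics
#'
#' One equivalent-weight unit is valued at one seventh of the mean grain
#' production value per hectare, the standard benefit-transfer convention:
#' `D = yield * price / 7` (currency/ha).
#'
#' @param grain_yield Mean grain yield, kg/ha (> 0).
#' @param grain_price Grain price, currency/kg (> 0).
#' @param divisor Grain-value divisor; the conventional 7 by default.
#' @return Base unit value `D` in currency per hectare.
#' @export
#' @examples
#' calibrate_unit_value(4405, 3.05)  # 1919.32 CNY/ha
calibrate_unit_value <- function(grain_yield, grain_price, divisor = 7) {
  if (grain_yield <= 0 || grain_price <= 0)
    stop("grain yield and price must be positive", call. = FALSE)
  grain_yield * grain_price / divisor
}

#' Build the value-coefficient table
#'
#' Converts dimensionless equivalent weights into monetary value
#' coefficients `VC[k, f] = weight[k, f] * D` (currency/ha/yr). The table
#' is always rebuilt from the weights; printed per-cell value tables are
#' not treated as authority.
#'
#' @param weights 7 x 9 weight matrix as from [equivalent_weights()].
#' @param D Base unit value, currency/ha (> 0).
#' @return A numeric matrix of class `value_table` with attribute
#'   `base_unit_value`.
#' @export
#' @examples
#' vc <- build_value_table(equivalent_weights(), 1919.32)
#' vc["Woodland", "GR"]  # 4510.402
build_value_table <- function(weights = equivalent_weights(),
                              D = calibrate_unit_value(4405, 3.05)) {
  if (D <= 0) stop("base unit value D must be positive", call. = FALSE)
  classes <- land_use_legend()$class
  services <- names(esv_services())
  miss <- which(is.na(weights[classes, services, drop = FALSE]), arr.ind = TRUE)
  if (nrow(miss))
    stop("missing weight for (", classes[miss[1, 1]], ", ",
         services[miss[1, 2]], ")", call. = FALSE)
  vc <- weights[classes, services, drop = FALSE] * D
  attr(vc, "base_unit_value") <- D
  class(vc) <- c("value_table", class(vc))
  vc
}

#' Static ESV totals from class areas
#'
#' The benefit-transfer aggregation: `ESV_f = sum_k A_k VC[k, f]` per
#' service, `ESV_k = sum_f A_k VC[k, f]` per class, and the static total
#' `ESV_s = sum_k sum_f A_k VC[k, f]`.
#'
#' @param areas Per-class areas in hectares: either the tibble from
#'   [tabulate_areas()] or a named numeric vector (names = classes).
#' @param vc Value-coefficient table from [build_value_table()].
#' @return List of class `esv_account`: `by_service` (named length-9),
#'   `by_class` (named length-7), `static` (scalar).
#' @export
esv_totals <- function(areas, vc) {
  if (is.data.frame(areas)) areas <- stats::setNames(areas$area_ha, areas$class)
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  a <- stats::setNames(rep(0, nrow(vc)), rownames(vc))
  unknown <- setdiff(names(areas), rownames(vc))
  if (length(unknown))
    stop("unknown land-use class: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  a[names(areas)] <- areas
  value <- a * unclass(vc)                 # A_k * VC_kf, class x service
  structure(list(by_service = colSums(value),
                 by_class = rowSums(value),
                 static = sum(value)),
            class = "esv_account")
}

#' @export
print.esv_account <- function(x, ...) {
  cat("<esv_account> static total:", format(x$static, big.mark = ","), "\n")
  invisible(x)
}

#' Deflate an economic series to the base year
#'
#' Removes year-over-year index growth so economic values are comparable
#' across years: `E_an(m) = E_m(m) / prod(index[base+1 .. m])`, with an
#' empty product at the base year (the base year is unchanged). Also
#' returns `E_avg`, the arithmetic mean of the deflated values over the
#' series, used to scale comparable ESV.
#'
#' @param socio A [socioeconomic_series()] tibble.
#' @param base_year Constant (base) year; must be the first usable year —
#'   deflation backwards from the base year is not supported.
#' @param measure Which column carries `E_m`; GDP by default, per-capita
#'   net income where available.
#' @return List with `series` (the input plus column `e_an`) and `e_avg`.
#' @export
deflate_series <- function(socio, base_year = min(socio$year),
                           measure = "gdp") {
  if (!base_year %in% socio$year)
    stop("base year ", base_year, " not in series", call. = FALSE)
  if (any(socio$year < base_year))
    stop("series contains years before the base year; ",
         "backward deflation is not supported", call. = FALSE)
  idx <- socio$gdp_index
  # empty product at the base year: cumulative product of indices after it
  cum <- cumprod(c(1, idx[-1]))
  e_an <- socio[[measure]] / cum
  out <- socio
  out$e_an <- e_an
  list(series = out, e_avg = mean(e_an))
}

#' Comparable ESV
#'
#' Rescales the static total onto the base-year economic level:
#' `ESV_c = ESV_s / E_avg * E_an`. When the year's deflated value equals
#' the period average, comparable and static ESV coincide.
#'
#' @param esv_static Static total(s), currency.
#' @param e_avg Period-average deflated economic value (> 0).
#' @param e_an Deflated economic value for the year(s).
#' @return Comparable ESV, same shape as `esv_static`.
#' @export
comparable_esv <- function(esv_static, e_avg, e_an) {
  if (any(e_avg <= 0)) stop("E_avg must be positive", call. = FALSE)
  esv_static / e_avg * e_an
}

#' Dynamic (willingness-to-pay) adjustment
#'
#' Social development raises willingness to pay for ecosystem services.
#' The development stage is `t = 1/En - 3` (En = Engel coefficient) and the
#' adjustment follows a Pearl logistic curve `Ac = 1 / (1 + exp(-t))`;
#' dynamic ESV is `ESV_d = ESV_c * Ac`. `Ac` is strictly decreasing in the
#' Engel coefficient and always lies in (0, 1).
#'
#' @param esv_comparable Comparable ESV value(s).
#' @param engel Engel coefficient(s) in (0, 1].
#' @return Tibble with columns `t`, `ac`, `esv_dynamic` (one row per input).
#' @export
#' @examples
#' dynamic_adjust(100, 1/3)  # t = 0, Ac = 0.5
dynamic_adjust <- function(esv_comparable, engel) {
  if (any(engel <= 0 | engel > 1))
    stop("Engel coefficient must lie in (0, 1]", call. = FALSE)
  t <- 1 / engel - 3
  ac <- 1 / (1 + exp(-t))
  tibble::tibble(t = t, ac = ac, esv_dynamic = esv_comparable * ac)
}

#' Per-pixel ESV raster
#'
#' Maps each land-use pixel to its total value coefficient
#' `sum_f VC[class, f]` (currency/ha/yr), optionally scaled by the pixel
#' area to a per-pixel value. No-data propagates as `NA`.
#'
#' @param grid Categorical [grid_raster()] on the package legend.
#' @param vc Value-coefficient table from [build_value_table()].
#' @param per `"hectare"` (default) or `"pixel"`.
#' @param legend Legend tibble mapping codes to classes.
#' @return A continuous [grid_raster()] (nodata = `NA`).
#' @export
esv_value_raster <- function(grid, vc, per = c("hectare", "pixel"),
                             legend = land_use_legend()) {
  per <- match.arg(per)
  row_value <- stats::setNames(rowSums(unclass(vc)), rownames(vc))
  code_value <- rep(NA_real_, max(legend$code))
  cls_known <- legend$class %in% names(row_value)
  if (!all(cls_known))
    stop("pixel class missing from value table: ",
         paste(legend$class[!cls_known], collapse = ", "), call. = FALSE)
  code_value[legend$code] <- row_value[legend$class]
  v <- grid$values
  keep <- valid_mask(grid)
  out <- matrix(NA_real_, nrow(v), ncol(v))
  out[keep] <- code_value[v[keep]]
  if (anyNA(out[keep]))
    stop("raster contains class codes missing from the value table",
         call. = FALSE)
  if (per == "pixel") out <- out * pixel_area_ha(grid)
  grid_raster(out, grid$xmin, grid$ymin, grid$cellsize, nodata = NA)
}

#' Per-year ESV accounts for a land-use series
#'
#' Runs the full valuation chain for every year: static totals from class
#' areas, GDP-index deflation to the base year, comparable ESV and the
#' dynamic willingness-to-pay adjustment.
#'
#' @param series A [land_use_series()].
#' @param socio A [socioeconomic_series()] covering the same years.
#' @param vc Value-coefficient table; by default calibrated from the
#'   series-mean grain yield and base-year grain price in `socio`.
#' @param base_year Constant/base year for deflation (first year).
#' @param mask Optional polygons restricting the valuation.
#' @return Tibble with one row per year: `year`, `esv_static`, `e_an`,
#'   `esv_comparable`, `t`, `ac`, `esv_dynamic`, plus per-service static
#'   columns prefixed `esv_`. Attribute `e_avg` carries the period mean.
#' @export
esv_accounts <- function(series, socio, vc = NULL,
                         base_year = min(socio$year), mask = NULL) {
  socio <- socioeconomic_series(socio)
  if (!all(series$years %in% socio$year))
    stop("socioeconomic series does not cover all raster years",
         call. = FALSE)
  if (is.null(vc)) {
    D <- calibrate_unit_value(mean(socio$grain_yield),
                              socio$grain_price[socio$year == base_year])
    vc <- build_value_table(equivalent_weights(), D)
  }
  defl <- deflate_series(socio, base_year)
  rows <- lapply(series$years, function(yr) {
    acc <- esv_totals(tabulate_areas(series, yr, mask), vc)
    s <- defl$series[defl$series$year == yr, ]
    esv_c <- comparable_esv(acc$static, defl$e_avg, s$e_an)
    dyn <- dynamic_adjust(esv_c, s$engel)
    tibble::tibble(year = yr, esv_static = acc$static, e_an = s$e_an,
                   esv_comparable = esv_c, t = dyn$t, ac = dyn$ac,
                   esv_dynamic = dyn$esv_dynamic,
                   !!!stats::setNames(as.list(acc$by_service),
                                      paste0("esv_", names(acc$by_service))))
  })
  out <- do.call(rbind, rows)
  attr(out, "e_avg") <- defl$e_avg
  out
}
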