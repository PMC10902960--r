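#' Ecosystem service types
#'
#' The nine ecosystem services priced by the valuation: gas regulation,
#' climate regulation, water supply, soil formation and retention, waste
#' treatment, biodiversity protection, food production, raw material and
#' recreation & culture.
#'
#' @return Named character vector: codes (`GR`, `CR`, `WS`, `SFR`, `WT`,
#'   `BP`, `F`, `RM`, `RC`) mapped to human-readable names.
#' @export
#' @examples
#' esv_services()
esv_services <- function() {
  c(GR  = "gas regulation",
    CR  = "climate regulation",
    WS  = "water supply",
    SFR = "soil formation and retention",
    WT  = "waste treatment",
    BP  = "biodiversity protection",
    F   = "food",
    RM  = "raw material",
    RC  = "recreation and culture")
}

#' Land-use legend
#'
#' The seven-class land-use/land-cover legend the valuation operates on.
#' Raster values are a bijection onto these codes; 255 is the default
#' no-data value and is never a class code.
#'
#' @return A tibble with columns `code` (integer raster value) and `class`.
#' @export
#' @examples
#' land_use_legend()
land_use_legend <- function() {
  tibble::tibble(
    code  = 1:7,
    class = c("Woodland", "Grassland", "Cropland", "Wetland",
              "Waterbody", "UnusedLand", "BuiltUp"))
}

#' Equivalent-weight table of ecosystem services
#'
#' Dimensionless equivalent-weight factors per (land-use class, service)
#' pair, adapted to an arid/semi-arid mining region. One weight unit equals
#' the base unit value `D` (one seventh of the mean grain production value
#' per hectare, see [calibrate_unit_value()]). Built-up land carries
#' negative weights for water supply, gas regulation and waste treatment:
#' impervious surfaces consume rather than provide those services.
#'
#' The Waterbody water-supply weight (20.97) is recovered from the row
#' total (50.24) minus the eight remaining cells; row totals are always
#' recomputed from cells rather than trusted from print (the Grassland
#' cells, for instance, sum to 5.57).
#'
#' @return A 7 x 9 numeric matrix, rows named by land-use class and columns
#'   by service code (see [esv_services()]).
#' @export
#' @examples
#' rowSums(equivalent_weights())
equivalent_weights <- function() {
  w <- rbind(
    Woodland   = c(2.35,  7.03,  0.37, 3.08, 1.99,  2.60, 0.10, 0.71, 1.14),
    Grassland  = c(0.51,  1.34,  0.08, 1.95, 0.44,  0.56, 0.30, 0.14, 0.25),
    Cropland   = c(0.67,  0.36,  0.02, 1.15, 0.10,  0.13, 0.85, 0.40, 0.06),
    Wetland    = c(1.91,  7.11,  5.50, 2.49, 3.60,  7.87, 0.51, 0.50, 4.73),
    Waterbody  = c(0.77, 14.62, 20.97, 0.41, 5.55,  2.55, 0.80, 0.23, 4.34),
    UnusedLand = c(0.00,  0.00,  0.02, 0.14, 0.01,  0.12, 0.01, 0.03, 0.01),
    BuiltUp    = c(-2.42, 0.00, -7.51, 0.02, -2.46, 0.00, 0.00, 0.00, 0.00))
  colnames(w) <- names(esv_services())
  w
}

#' Trend classes
#'
#' Ordered labels for the five-way Theil-Sen / Mann-Kendall trend
#' classification. Integer codes 1..5 in this order are used in class
#' rasters.
#'
#' @return Character vector of the five class labels.
#' @export
trend_classes <- function() {
  c("SignificantIncrease", "SlightIncrease", "NoTrend",
    "SlightDecrease", "SignificantDecrease")
}

#' Validate a socioeconomic series
#'
#' Checks and normalises the per-year socioeconomic table that drives the
#' dynamic ESV adjustment: GDP (`gdp`), yearly GDP index (`gdp_index`,
#' ratio to the previous year), Engel coefficient (`engel`, fraction of
#' household expenditure on food, in (0, 1]), grain yield (kg/ha) and
#' grain price (currency/kg).
#'
#' @param x A data frame with columns `year`, `gdp`, `gdp_index`, `engel`,
#'   `grain_yield`, `grain_price`.
#' @return The series as a tibble, invisibly checked: years strictly
#'   increasing and contiguous, `gdp_index > 0`, `0 < engel <= 1`.
#' @export
socioeconomic_series <- function(x) {
  need <- c("year", "gdp", "gdp_index", "engel", "grain_yield", "grain_price")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("socioeconomic series is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- tibble::as_tibble(x)[need]
  if (any(diff(x$year) != 1))
    stop("years must be strictly increasing and contiguous", call. = FALSE)
  if (any(x$gdp_index <= 0))
    stop("gdp_index must be positive", call. = FALSE)
  if (any(x$engel <= 0 | x$engel > 1))
    stop("engel coefficient must lie in (0, 1]", call. = FALSE)
  x
}
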