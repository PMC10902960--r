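#' Synthetic mining-landscape configuration
#'
#' Defines the study conditions the generator emulates: a
#' grassland-dominated arid/semi-arid mosaic (grassland above 75% of the
#' area) observed annually over 1990-2020, with opencast mining expanding
#' inside concession polygons from a start year and optional late-period
#' restoration. The seed fully determines the output.
#'
#' @param nrow,ncol Grid shape in pixels.
#' @param cellsize Pixel edge in metres (250 m gives 6.25 ha pixels).
#' @param years Observation years.
#' @param proportions Named base-mosaic class proportions (must sum to 1).
#' @param n_nuclei Number of patch nuclei for the region-growing mosaic.
#' @param n_concessions Number of rectangular mining concessions.
#' @param concession_frac Fraction of the study area per concession.
#' @param mining_start Year mining expansion begins (cumulative mined area
#'   in year m is `min(expansion_ha * (m - mining_start), concession area)`).
#' @param expansion_ha Mined area added per year, hectares (all
#'   concessions combined). The default (`NA`) resolves to 4% of the total
#'   concession area per year — 720 ha/yr on the default grid — so the
#'   scenario scales with the grid.
#' @param builtup_frac Fraction of the mining footprint encoded as
#'   built-up (infrastructure fringe); the rest is unused (disturbed bare)
#'   land — the legend has no mining class, so disturbance is priced
#'   through these classes.
#' @param restoration_start First year of restoration (`NA` disables it).
#' @param restoration_rate Fraction of the currently mined footprint
#'   restored to grassland per year.
#' @param noise_rate Annual per-pixel probability of a spurious class flip
#'   outside concessions (classification noise).
#' @param seed RNG seed.
#' @return List of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 120, ncol = 120, cellsize = 250,
                             years = 1990:2020,
                             proportions = c(Grassland = 0.76,
                                             Woodland = 0.08,
                                             Cropland = 0.08,
                                             Wetland = 0.01,
                                             Waterbody = 0.01,
                                             UnusedLand = 0.04,
                                             BuiltUp = 0.02),
                             n_nuclei = 150,
                             n_concessions = 2, concession_frac = 0.10,
                             mining_start = 2000, expansion_ha = NA,
                             builtup_frac = 0.05,
                             restoration_start = 2016,
                             restoration_rate = 0.03,
                             noise_rate = 0.001, seed = 42) {
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1", call. = FALSE)
  if (!all(names(proportions) %in% land_use_legend()$class))
    stop("unknown class in proportions", call. = FALSE)
  if (is.na(expansion_ha))
    expansion_ha <- 0.04 * n_concessions * concession_frac * nrow * ncol *
      cellsize^2 / 1e4
  structure(as.list(environment()), class = "landscape_config")
}

#' Generate an annual land-use raster series with mining expansion
#'
#' Builds a base mosaic by seeded region growing (class-labelled nuclei,
#' pixels take the class of their nearest nucleus), places rectangular
#' mining concessions, then evolves the landscape year by year: a
#' configured area inside the concessions converts to unused/built-up land
#' (the mining footprint, growing outward from each concession centre),
#' after the restoration year a configured fraction of the footprint
#' reverts to grassland, and outside the concessions a small background
#' noise rate flips pixel classes. Deterministic per seed; expansion
#' demand beyond the concession area is capped with a warning.
#'
#' @param config A [landscape_config()].
#' @return List with `series` (a [land_use_series()]), `concessions`
#'   (list of polygons), `study` (study-boundary polygon), `mined_area_ha`
#'   (named per-year cumulative mined area), `class_log` (tibble of
#'   per-year per-class pixel counts — the conservation bookkeeping) and
#'   the `config`.
#' @export
generate_landscape_series <- function(config = landscape_config()) {
  cf <- config
  legend <- land_use_legend()
  code_of <- stats::setNames(legend$code, legend$class)
  nr <- cf$nrow; nc <- cf$ncol; px_ha <- cf$cellsize^2 / 1e4

  withr::with_seed(cf$seed, {
    # --- base mosaic: nearest-nucleus (Voronoi) patches -------------------
    quota <- round(cf$proportions * cf$n_nuclei)
    quota[1] <- quota[1] + cf$n_nuclei - sum(quota)
    nuc_class <- rep(names(quota), quota)
    nuc <- cbind(stats::runif(cf$n_nuclei, 0, nc),
                 stats::runif(cf$n_nuclei, 0, nr))
    cx <- matrix(seq_len(nc) - 0.5, nr, nc, byrow = TRUE)
    cy <- matrix(nr - seq_len(nr) + 0.5, nr, nc)
    nearest <- max.col(-outer(as.vector(cx), nuc[, 1], `-`)^2 -
                         outer(as.vector(cy), nuc[, 2], `-`)^2)
    base <- matrix(code_of[nuc_class[nearest]], nr, nc)

    # --- concessions: rectangles in separate quadrants --------------------
    side_px <- sqrt(cf$concession_frac * nr * nc)
    conc <- vector("list", cf$n_concessions)
    conc_mask <- matrix(FALSE, nr, nc)
    for (i in seq_len(cf$n_concessions)) {
      qx <- (i - 1) %% 2; qy <- ((i - 1) %/% 2) %% 2
      lo_x <- qx * nc / 2 + 2; hi_x <- max((qx + 1) * nc / 2 - side_px - 2, lo_x)
      lo_y <- qy * nr / 2 + 2; hi_y <- max((qy + 1) * nr / 2 - side_px - 2, lo_y)
      x0 <- stats::runif(1, lo_x, hi_x)
      y0 <- stats::runif(1, lo_y, hi_y)
      conc[[i]] <- cbind(x = c(x0, x0 + side_px, x0 + side_px, x0),
                         y = c(y0, y0, y0 + side_px, y0 + side_px)) *
        cf$cellsize
      inx <- cx >= x0 & cx < x0 + side_px & cy >= y0 & cy < y0 + side_px
      conc_mask <- conc_mask | inx
    }
    cap_ha <- sum(conc_mask) * px_ha

    # mining order: outward from the nearest concession centre
    centres <- t(vapply(conc, function(p) colMeans(p[, 1:2]) / cf$cellsize,
                        numeric(2)))
    d2 <- Reduce(pmin, lapply(seq_len(nrow(centres)), function(i)
      (as.vector(cx) - centres[i, 1])^2 + (as.vector(cy) - centres[i, 2])^2))
    mine_order <- which(as.vector(conc_mask))[order(d2[as.vector(conc_mask)])]
    builtup_pick <- seq_along(mine_order) %% round(1 / cf$builtup_frac) == 0

    # --- year-by-year evolution -------------------------------------------
    rasters <- vector("list", length(cf$years))
    mined_ha <- stats::setNames(numeric(length(cf$years)), cf$years)
    cur <- base
    capped <- FALSE
    n_mined <- 0L
    n_restored <- 0L
    for (j in seq_along(cf$years)) {
      yr <- cf$years[j]
      if (yr > cf$mining_start) {
        demand <- cf$expansion_ha * (yr - cf$mining_start)
        if (demand > cap_ha && !capped) {
          warning("mining expansion demand exceeds concession area; capped",
                  call. = FALSE)
          capped <- TRUE
        }
        target <- round(min(demand, cap_ha) / px_ha)
        if (target > n_mined) {
          new_idx <- (n_mined + 1):target
          cur[mine_order[new_idx]] <-
            ifelse(builtup_pick[new_idx], code_of["BuiltUp"],
                   code_of["UnusedLand"])
          n_mined <- target
        }
      }
      if (!is.na(cf$restoration_start) && yr >= cf$restoration_start &&
          n_mined > n_restored) {
        k <- round(cf$restoration_rate * (n_mined - n_restored))
        if (k > 0) {
          cur[mine_order[(n_restored + 1):(n_restored + k)]] <-
            code_of["Grassland"]
          n_restored <- n_restored + k
        }
      }
      if (cf$noise_rate > 0 && j > 1) {
        outside <- which(!as.vector(conc_mask))
        flip <- outside[stats::runif(length(outside)) < cf$noise_rate]
        if (length(flip))
          cur[flip] <- sample(legend$code, length(flip), replace = TRUE)
      }
      mined_ha[j] <- (n_mined - n_restored) * px_ha
      rasters[[j]] <- grid_raster(cur, xmin = 0, ymin = 0,
                                  cellsize = cf$cellsize, nodata = 255)
    }
  })

  class_log <- do.call(rbind, lapply(seq_along(cf$years), function(j)
    tibble::tibble(year = cf$years[j], class = legend$class,
                   pixels = tabulate(factor(rasters[[j]]$values,
                                            levels = legend$code),
                                     nbins = nrow(legend)))))
  study <- cbind(x = c(0, nc, nc, 0), y = c(0, 0, nr, nr)) * cf$cellsize
  list(series = land_use_series(rasters, cf$years),
       concessions = conc, study = study,
       mined_area_ha = mined_ha, class_log = class_log, config = cf)
}

#' Generate a plausible socioeconomic series
#'
#' GDP compounds at a stated growth rate (with optional lognormal noise);
#' the yearly GDP index is the realised year-over-year ratio, so the
#' cumulative product of indices telescopes to `GDP(last)/GDP(first)`. The
#' Engel coefficient declines linearly from `engel_start` to `engel_end`
#' (development raises willingness to pay over the period). Grain yield
#' and price are held constant at their stated values.
#'
#' @param years Calendar years.
#' @param gdp0 First-year GDP (currency).
#' @param gdp_growth Annual GDP growth rate.
#' @param gdp_noise_sd SD of lognormal noise on the yearly growth factor.
#' @param engel_start,engel_end Engel coefficient at the first/last year,
#'   each in (0, 1].
#' @param grain_yield Grain yield, kg/ha.
#' @param grain_price Grain price, currency/kg.
#' @param seed RNG seed.
#' @return A [socioeconomic_series()] tibble.
#' @export
generate_socioeconomic_series <- function(years, gdp0 = 1e6,
                                          gdp_growth = 0.09,
                                          gdp_noise_sd = 0,
                                          engel_start = 0.55,
                                          engel_end = 0.28,
                                          grain_yield = 4405,
                                          grain_price = 3.05, seed = 1) {
  if (any(c(engel_start, engel_end) <= 0 | c(engel_start, engel_end) > 1))
    stop("Engel coefficients must lie in (0, 1]", call. = FALSE)
  if (gdp0 <= 0 || gdp_growth <= -1)
    stop("invalid GDP parameters", call. = FALSE)
  n <- length(years)
  fac <- withr::with_seed(seed,
    (1 + gdp_growth) * exp(stats::rnorm(n - 1, 0, gdp_noise_sd)))
  gdp <- gdp0 * cumprod(c(1, fac))
  socioeconomic_series(tibble::tibble(
    year = years,
    gdp = gdp,
    gdp_index = c(1, gdp[-1] / gdp[-n]),
    engel = seq(engel_start, engel_end, length.out = n),
    grain_yield = grain_yield,
    grain_price = grain_price))
}

#' Generate a piecewise log-linear test series
#'
#' `y(t)` follows the exponential of a continuous piecewise-linear
#' log-trend whose segment slopes are `ln(1 + APC/100)`, plus Gaussian
#' noise on the log scale — the data-generating model of the joinpoint
#' stage, used to exercise and validate it.
#'
#' @param years Observation years.
#' @param breaks Breakpoint years, strictly inside `range(years)`.
#' @param apcs Per-segment annual percentage changes (length
#'   `length(breaks) + 1`, each > -100).
#' @param start_value Value at the first year (> 0).
#' @param log_noise_sd SD of the Gaussian log-scale noise.
#' @param seed RNG seed.
#' @return Tibble with `year` and `value`.
#' @export
generate_piecewise_series <- function(years, breaks = numeric(0), apcs,
                                      start_value = 100, log_noise_sd = 0,
                                      seed = 1) {
  if (length(apcs) != length(breaks) + 1)
    stop("need one APC per segment (breaks + 1)", call. = FALSE)
  if (any(apcs <= -100)) stop("APC must exceed -100%", call. = FALSE)
  if (length(breaks) &&
      (any(breaks <= min(years)) || any(breaks >= max(years)) ||
       is.unsorted(breaks, strictly = TRUE)))
    stop("breaks must be strictly increasing and inside the year range",
         call. = FALSE)
  slopes <- log(1 + apcs / 100)
  logy <- log(start_value) + slopes[1] * (years - years[1])
  if (length(breaks))
    for (j in seq_along(breaks))
      logy <- logy + (slopes[j + 1] - slopes[j]) * pmax(years - breaks[j], 0)
  noise <- withr::with_seed(seed, stats::rnorm(length(years), 0, log_noise_sd))
  tibble::tibble(year = years, value = exp(logy + noise))
}
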