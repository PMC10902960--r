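#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: the synthetic scenario
#' (or paths to pre-existing inputs), valuation base year, trend
#' thresholds, joinpoint search depth, sampling design and output
#' directory. The configuration is serialised alongside the outputs for
#' provenance.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for every stochastic stage.
#' @param landscape A [landscape_config()]; its own seed is overridden by
#'   `seed`.
#' @param input_dir Optional directory of pre-existing inputs
#'   (`landuse_<year>.asc`, `concessions.geojson`, `study.geojson`,
#'   `socioeconomic.csv`) used instead of simulation.
#' @param gdp_growth,engel_start,engel_end Socioeconomic scenario.
#' @param base_year Constant/base year for deflation (first year if `NA`).
#' @param beta_threshold,z_threshold Trend-classification thresholds.
#' @param max_joinpoints Joinpoint search depth.
#' @param n_points Number of comparison sample points.
#' @param buffer_radius Sample-point buffer radius, metres.
#' @param cell_size Grid-aggregation cell, metres.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            landscape = landscape_config(),
                            input_dir = NULL,
                            gdp_growth = 0.09, engel_start = 0.55,
                            engel_end = 0.28, base_year = NA,
                            beta_threshold = 0.005, z_threshold = 2.58,
                            max_joinpoints = 2, n_points = 300,
                            buffer_radius = 1000, cell_size = 10000) {
  landscape$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> valuation -> trend -> joinpoint ->
#' compare, writing every result to `config$out_dir`: the socioeconomic
#' series and per-year ESV accounts (CSV), first/last-year dynamic-ESV and
#' trend beta/Z/class rasters (ESRI ASCII grid), the trend-class area
#' summary (CSV), joinpoint reports for the mining-impact and control
#' regions (JSON), the sample-point comparison (CSV), sample points and
#' polygons (GeoJSON) and a machine-readable run manifest (JSON). Rerunning
#' with the same config and seed reproduces every output bit for bit.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with the in-memory results (`accounts`,
#'   `trend_summary`, `joinpoint`, `comparison`, `outputs`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    say("stage %-10s %.2fs", name, timings[[name]])
    out
  }

  # ---- simulate or load ----------------------------------------------------
  world <- stage("simulate", {
    if (is.null(config$input_dir)) {
      generate_landscape_series(config$landscape)
    } else {
      load_pipeline_inputs(config$input_dir, config$landscape$years)
    }
  })
  series <- world$series
  years <- series$years

  socio <- stage("socio", {
    if (is.null(config$input_dir) || is.null(world$socio)) {
      generate_socioeconomic_series(years, gdp_growth = config$gdp_growth,
                                    engel_start = config$engel_start,
                                    engel_end = config$engel_end,
                                    seed = config$seed)
    } else world$socio
  })
  base_year <- if (is.na(config$base_year)) min(socio$year) else
    config$base_year

  # ---- valuation -----------------------------------------------------------
  D <- calibrate_unit_value(mean(socio$grain_yield),
                            socio$grain_price[socio$year == base_year])
  vc <- build_value_table(equivalent_weights(), D)
  val <- stage("value", {
    defl <- deflate_series(socio, base_year)
    accounts <- esv_accounts(series, socio, vc, base_year)
    # per-pixel dynamic ESV: static per-hectare raster scaled by the
    # year's comparable/dynamic multiplier (valuation is linear in area)
    mult <- accounts$e_an / attr(accounts, "e_avg") * accounts$ac
    stacks <- lapply(seq_along(years), function(j) {
      g <- esv_value_raster(series$rasters[[j]], vc, per = "hectare")
      g$values <- g$values * mult[j]
      g
    })
    list(accounts = accounts, stacks = stacks)
  })

  # ---- trend ---------------------------------------------------------------
  trend <- stage("trend", {
    tr <- trend_raster(val$stacks, years,
                       beta_threshold = config$beta_threshold,
                       z_threshold = config$z_threshold)
    tr$summary <- summarize_classes(tr$class)
    tr
  })

  # ---- joinpoint -----------------------------------------------------------
  jp <- stage("joinpoint", {
    acc_mining <- esv_accounts(series, socio, vc, base_year,
                               mask = world$concessions)
    # valuation is linear in area and the concessions partition the study
    # area, so control = total - mining
    dyn <- list(mining_impact = acc_mining$esv_dynamic,
                control = val$accounts$esv_dynamic -
                  acc_mining$esv_dynamic)
    lapply(names(dyn), function(grp) {
      fit <- select_model(years, dyn[[grp]],
                          max_joinpoints = config$max_joinpoints)
      list(group = grp, series = dyn[[grp]], fit = fit,
           apc = apc(fit), aapc = aapc(fit))
    }) |> stats::setNames(names(dyn))
  })

  # ---- compare -------------------------------------------------------------
  cmp <- stage("compare", {
    pts <- sample_points(world$study, world$concessions,
                         n = config$n_points, seed = config$seed)
    per_year <- lapply(c(1, length(years)), function(j) {
      ex <- buffer_extract(val$stacks[[j]], pts,
                           radius = config$buffer_radius)
      cbind(year = years[j], compare_groups(ex))
    })
    agg <- grid_aggregate(val$stacks[[length(years)]],
                          cell_size = config$cell_size)
    list(points = pts, table = do.call(rbind, per_year), grid = agg)
  })

  # ---- write outputs -------------------------------------------------------
  outputs <- stage("write", {
    od <- config$out_dir
    paths <- c(
      socioeconomic = file.path(od, "socioeconomic.csv"),
      accounts = file.path(od, "esv_accounts.csv"),
      trend_summary = file.path(od, "trend_class_areas.csv"),
      comparison = file.path(od, "comparison.csv"),
      beta = file.path(od, "trend_beta.asc"),
      z = file.path(od, "trend_z.asc"),
      class = file.path(od, "trend_class.asc"),
      esv_first = file.path(od, sprintf("esv_dynamic_%d.asc", years[1])),
      esv_last = file.path(od, sprintf("esv_dynamic_%d.asc",
                                       years[length(years)])),
      points = file.path(od, "sample_points.geojson"),
      concessions = file.path(od, "concessions.geojson"),
      joinpoint = file.path(od, "joinpoint.json"),
      manifest = file.path(od, "manifest.json"))
    utils::write.csv(socio, paths["socioeconomic"], row.names = FALSE)
    utils::write.csv(val$accounts, paths["accounts"], row.names = FALSE)
    utils::write.csv(trend$summary, paths["trend_summary"],
                     row.names = FALSE)
    utils::write.csv(cmp$table, paths["comparison"], row.names = FALSE)
    write_ascii_grid(trend$beta, paths["beta"])
    write_ascii_grid(trend$z, paths["z"])
    write_ascii_grid(trend$class, paths["class"])
    write_ascii_grid(val$stacks[[1]], paths["esv_first"])
    write_ascii_grid(val$stacks[[length(years)]], paths["esv_last"])
    pt_polys <- lapply(seq_len(nrow(cmp$points)), function(i)
      point_square(cmp$points$x[i], cmp$points$y[i], 1))
    write_geojson(pt_polys, paths["points"],
                  properties = as.data.frame(cmp$points[c("id", "group")]))
    write_geojson(world$concessions, paths["concessions"])
    jp_report <- lapply(jp, function(g)
      list(group = g$group,
           breakpoints = g$fit$breakpoints,
           apc = g$apc, aapc = g$aapc))
    jsonlite::write_json(jp_report, paths["joinpoint"], auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    manifest <- list(
      package = "esvtrend",
      version = as.character(utils::packageVersion("esvtrend")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      base_year = base_year,
      unit_value = D,
      config = config_as_list(config),
      timings_sec = timings,
      outputs = as.list(basename(paths)))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths
  })

  say("pipeline done in %.1fs", as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")))
  invisible(list(accounts = val$accounts, trend_summary = trend$summary,
                 joinpoint = jp, comparison = cmp$table,
                 outputs = outputs))
}

point_square <- function(x, y, half) {
  cbind(x = c(x - half, x + half, x + half, x - half),
        y = c(y - half, y - half, y + half, y + half))
}

config_as_list <- function(config) {
  cf <- unclass(config)
  cf$landscape <- unclass(cf$landscape)
  cf$landscape$proportions <- as.list(cf$landscape$proportions)
  cf
}

#' Load pre-existing pipeline inputs from a directory
#'
#' Expects `landuse_<year>.asc` for every requested year,
#' `concessions.geojson`, `study.geojson` and optionally
#' `socioeconomic.csv`. A missing year's raster aborts with an error naming
#' the year.
#'
#' @param dir Input directory.
#' @param years Years to load.
#' @return List with `series`, `concessions`, `study` and (optionally)
#'   `socio` — the same shape [generate_landscape_series()] returns.
#' @export
load_pipeline_inputs <- function(dir, years) {
  paths <- file.path(dir, sprintf("landuse_%d.asc", years))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing land-use raster for year ",
         paste(years[missing], collapse = ", "), call. = FALSE)
  rasters <- lapply(paths, function(p) {
    g <- read_ascii_grid(p)
    g$values <- matrix(as.integer(g$values), nrow(g$values))
    g$nodata <- 255
    g
  })
  socio_path <- file.path(dir, "socioeconomic.csv")
  list(series = land_use_series(rasters, years),
       concessions = read_geojson(file.path(dir, "concessions.geojson"))$polygons,
       study = read_geojson(file.path(dir, "study.geojson"))$polygons[[1]],
       socio = if (file.exists(socio_path))
         socioeconomic_series(utils::read.csv(socio_path)) else NULL)
}
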