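#' Default pipeline configuration
#'
#' One list configures the whole synthetic run: a single master seed
#' governs every stage (each stage derives its own substream via
#' [stage_seed()]), so any stage can be rerun individually and the full
#' bundle is reproducible byte-for-byte.
#'
#' The defaults describe a small but complete world: a 12 x 24 grid, six
#' countries, five taxa spanning trophic levels 2-4.5, ten production
#' years, 30% of production exported, and a 1950-2011 consumption history
#' projected to 2100.
#'
#' @param seed Master seed.
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    grid = list(n_lat = 12, n_lon = 24, land_fraction = 0.3,
                depth_min = 10, depth_max = 4000),
    pp = list(years = 1998:2007, mean_pp = 150, spatial_cv = 0.4,
              interannual_cv = 0.05),
    world = list(n_countries = 6, eez_fraction = 0.8, n_ports = 2,
                 taxa = list(
                   list(taxon = "smallpelagic", tl = 2.5),
                   list(taxon = "shrimp", tl = 2.7),
                   list(taxon = "cod", tl = 4.1),
                   list(taxon = "tuna", tl = 4.5),
                   list(taxon = "mollusc", tl = 2.0))),
    catches = list(years = 2000:2009, effort_trend = 0.02,
                   target_ppr_fraction = 0.12, coverage = 0.8),
    trade = list(export_fraction = 0.3, mariculture_tonnes = 2000),
    mc = list(n_trials = 500),
    bootstrap = list(n_trials = 200, n_samples = 2000),
    supply = list(ffm_scenarios = c(0.10, 0.07, 0.05), n_sims = 1000),
    projection = list(horizon = 2100)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default. The file's `seed` (if any) is overridden by the `seed`
#' argument when supplied.
#'
#' @param path YAML file path.
#' @param seed Optional master-seed override.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  cfg <- default_run_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]]) && nm != "world") {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else if (nm == "world") {
      for (k in names(user$world)) cfg$world[[k]] <- user$world[[k]]
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full synthetic footprint pipeline
#'
#' Executes every stage in dependency order — world generation, catches and
#' trade, PPR footprint (bands, accessible percentage with Monte Carlo,
#' EEZ summary), sourcing-distance bootstrap, supply limits and demand
#' projection — and returns the result bundle. When `out_dir` is given the
#' bundle is also written as CSV/JSON; outputs are staged in a temporary
#' directory and only moved into `out_dir` once every stage has succeeded,
#' so a failed run leaves no partial bundle. Any stage error is re-thrown
#' with the stage name attached.
#'
#' @param config A `run_config` list.
#' @param out_dir Optional output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return A list of class `of_bundle` with elements `distance`, `bands`,
#'   `accessible`, `accessible_mc`, `supply`, `supply_sensitivity`,
#'   `projection`, `crossings`, `eez`, and `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         quiet = FALSE) {
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  grid <- stage("grid", generate_grid(
    config$grid$n_lat, config$grid$n_lon, config$grid$land_fraction,
    list(min = config$grid$depth_min, max = config$grid$depth_max),
    seed = stage_seed(seed, "grid")))
  say("grid: %d sea cells", sum(grid$cells$sea))

  pp <- stage("pp_fields", generate_pp_fields(
    grid, config$pp$years, config$pp$mean_pp, config$pp$spatial_cv,
    config$pp$interannual_cv, seed = stage_seed(seed, "pp")))

  taxa <- bind_rows(lapply(config$world$taxa, as_tibble))
  world <- stage("world", generate_world(
    grid, config$world$n_countries, taxa,
    eez_fraction = config$world$eez_fraction,
    n_ports = config$world$n_ports, seed = stage_seed(seed, "world")))
  say("world: %d countries, %d ports", length(world$countries),
      nrow(world$ports))

  catches <- stage("catches", generate_catches(
    world, grid, pp, config$catches$years, config$catches$effort_trend,
    config$catches$target_ppr_fraction, config$catches$coverage,
    seed = stage_seed(seed, "catches")))
  say("catches: %d records, %.3g t", nrow(catches), sum(catches$tonnage))

  mar <- stats::setNames(rep(config$trade$mariculture_tonnes,
                             length(world$countries)), world$countries)
  trade <- stage("trade", generate_trade(
    world, catches, mar, config$trade$export_fraction,
    seed = stage_seed(seed, "trade")))
  # conservation check, logged at stage granularity
  wild_traded <- sum(trade$tonnage[trade$source_kind == "wild"])
  stopifnot(wild_traded <= sum(catches$tonnage) + 1e-6)
  say("trade: %d flows, wild traded %.3g t", nrow(trade), wild_traded)

  pparams <- ppr_params()
  rb <- stage("ppr_bands", ratio_and_bands(catches, pp, grid, world$taxa,
                                           pparams))
  acc <- stage("ppr_accessible",
               accessible_percentage(catches, pp, grid, world$taxa, pparams))
  acc_mc <- stage("ppr_mc", mc_accessible_percentage(
    catches, pp, grid, world$taxa,
    mc_config(n_trials = config$mc$n_trials,
              seed = stage_seed(seed, "mc")), pparams))

  dist_tabs <- stage("distance", {
    wild_exports <- trade[trade$source_kind == "wild", ]
    m <- match_exports_to_catches(catches, wild_exports)
    mar_trade <- trade[trade$source_kind == "mariculture", ]
    mar_imports <- tibble(year = mar_trade$year,
                          origin = mar_trade$origin_country,
                          importer = mar_trade$importer,
                          tonnage = mar_trade$tonnage)
    years <- sort(unique(catches$year))
    mar_dom <- tibble(
      year = rep(years, each = length(mar)),
      country = rep(names(mar), times = length(years)),
      tonnage = rep(mar * (1 - config$trade$export_fraction),
                    times = length(years)))
    records <- assemble_distance_records(world, grid, m$matched, catches,
                                         mar_dom, mar_imports)
    series <- distance_series(records,
                              n_trials = config$bootstrap$n_trials,
                              n_samples = config$bootstrap$n_samples,
                              seed = stage_seed(seed, "bootstrap"))
    list(records = records, series = series)
  })
  say("distance: %d records over %d years", nrow(dist_tabs$records),
      nrow(dist_tabs$series))

  eez <- stage("eez_summary", {
    cons <- vapply(split(dist_tabs$records$tonnage,
                         dist_tabs$records$country), sum, numeric(1))
    n_years <- length(unique(catches$year))
    cons <- cons / max(n_years, 1)
    pop_last <- world$population[world$population$year ==
                                   max(world$population$year), ]
    popv <- stats::setNames(pop_last$population, pop_last$country)
    eez_summary(catches, pp, world, world$taxa, pparams,
                consumption_by_country = cons[names(cons) %in% names(popv)],
                population_by_country = popv)
  })

  supply <- stage("supply", supply_scenarios(config$supply$ffm_scenarios))
  sens <- stage("supply_sensitivity", bind_rows(lapply(
    config$supply$ffm_scenarios, function(f) {
      supply_sensitivity(ffm_scenario = f, n_sims = config$supply$n_sims,
                         seed = stage_seed(seed, paste0("sens_", f)))
    })))

  proj_tabs <- stage("projection", {
    scen <- generate_population(seed = stage_seed(seed, "population"))
    fit <- fit_consumption_model(scen$historical$population,
                                 scen$historical$consumption)
    proj <- project_consumption(fit, scen, config$projection$horizon)
    crossings <- bind_rows(lapply(seq_len(nrow(supply)), function(i) {
      cbind(tibble(ffm = supply$ffm[i]),
            limit_crossing_year(proj, supply$S[i] * 1e6))
    }))
    list(fit = fit, projection = proj, crossings = crossings)
  })

  manifest <- list(
    package = "oceanfootprint",
    version = as.character(utils::packageVersion("oceanfootprint")),
    seed = seed,
    config_hash = config_hash(config),
    tables = list(
      distance_series = "distance", band_areas = "ppr_bands",
      accessible = "ppr_accessible", accessible_mc = "ppr_mc",
      eez_summary = "eez_summary", supply_limits = "supply",
      supply_sensitivity = "supply_sensitivity",
      demand_projection = "projection", limit_crossings = "projection")
  )

  bundle <- structure(list(
    distance = dist_tabs$series, distance_records = dist_tabs$records,
    bands = rb$bands, accessible = acc, accessible_mc = acc_mc,
    eez = eez, supply = supply, supply_sensitivity = sens,
    projection = proj_tabs$projection, crossings = proj_tabs$crossings,
    fit = proj_tabs$fit, manifest = manifest
  ), class = "of_bundle")

  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Stable hash of the configuration: md5 of its canonical JSON rendering.
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a result bundle to disk
#'
#' All tables go to CSV, the manifest to JSON. Tables are staged in a
#' temporary directory and moved atomically so `out_dir` never holds a
#' partial bundle; the manifest is written last.
#'
#' @param bundle An `of_bundle` from [run_pipeline()].
#' @param out_dir Target directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "of_bundle"))
  staging <- tempfile("bundle_")
  dir.create(staging, recursive = TRUE)
  tabs <- c("distance", "distance_records", "bands", "accessible",
            "accessible_mc", "eez", "supply", "supply_sensitivity",
            "projection", "crossings")
  paths <- character(0)
  for (nm in tabs) {
    p <- file.path(staging, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(staging, "manifest.json")
  writeLines(jsonlite::toJSON(bundle$manifest, auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), p)
  paths <- c(paths, p)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- file.copy(paths, out_dir, overwrite = TRUE)
  stopifnot(all(ok))
  unlink(staging, recursive = TRUE)
  invisible(file.path(out_dir, basename(paths)))
}

#' @export
print.of_bundle <- function(x, ...) {
  cat("<of_bundle>\n")
  cat(sprintf("  distance series: %d years\n", nrow(x$distance)))
  cat(sprintf("  band areas: %d years\n", nrow(x$bands)))
  cat(sprintf("  supply limits (Mt): %s\n",
              paste(round(x$supply$S), collapse = ", ")))
  cat(sprintf("  config hash: %s\n", x$manifest$config_hash))
  invisible(x)
}
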