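# Declarative configuration and tidy CSV output helpers.

#' Load a world configuration from a YAML file
#'
#' The file mirrors the fields of [load_world()]'s return value; vector
#' fields (`temp_rise_C`, `precip_change_frac`) are maps with `annual`,
#' `monsoon` and `dry` keys. Fields not present fall back to the values
#' of the named base world.
#'
#' @param path YAML file path
#' @param base world name the file overrides (default "positive")
#' @return a `world_config`
#' @export
load_scenario_config <- function(path, base = "positive") {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  vals <- yaml::read_yaml(path)
  config <- unclass(load_world(base))
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (nm %in% c("temp_rise_C", "precip_change_frac"))
      v <- unlist(v)[c("annual", "monsoon", "dry")]
    config[[nm]] <- v
  }
  validate_world(config)
  structure(config, class = "world_config")
}

#' Write the driver series of a world as tidy CSV
#'
#' Emits one file, `drivers.csv`, with columns `year`, `variable`,
#' `value`, `unit` covering sea level, population, the economic index,
#' embankment height and annual climate summaries.
#'
#' @param config a `world_config`
#' @param climatology baseline climatology ([make_climatology()])
#' @param out_dir output directory (created if needed)
#' @param years years covered
#' @param initial_embankment_cm initial embankment height
#' @return the file path, invisibly
#' @export
write_driver_series <- function(config, climatology, out_dir,
                                years = 1985:2055,
                                initial_embankment_cm = 150) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- annual_climate(generate_climate(config, climatology, years = years))
  emb_years <- 2015:max(years)
  tidy <- rbind(
    data.frame(year = years, variable = "slr", unit = "cm",
               value = slr_series(config, years)$slr_cm),
    data.frame(year = years, variable = "population", unit = "millions",
               value = population_series(config, years)$population_millions),
    data.frame(year = years, variable = "econ_index", unit = "1",
               value = econ_index(config, 2015, years)$econ_index),
    data.frame(year = emb_years, variable = "embankment_height", unit = "cm",
               value = embankment_series(initial_embankment_cm, config,
                                         emb_years)$height_cm),
    data.frame(year = years, variable = "temp", unit = "C",
               value = ann$temp_C),
    data.frame(year = years, variable = "precip", unit = "mm/yr",
               value = ann$precip_mm),
    data.frame(year = years, variable = "rice_salt_tolerance", unit = "dS/m",
               value = rice_tolerance(config, years))
  )
  path <- file.path(out_dir, "drivers.csv")
  utils::write.csv(tidy[, c("year", "variable", "value", "unit")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Write ensemble indicator tables, sensitivity and attribution as CSV
#'
#' @param results [run_ensemble()] output
#' @param runs the run table
#' @param out_dir output directory
#' @return invisibly, the paths written
#' @export
write_ensemble_outputs <- function(results, runs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(manifest = file.path(out_dir, "runs.csv"),
             indicators = file.path(out_dir, "indicators.csv"),
             sensitivity = file.path(out_dir, "sensitivity.csv"))
  utils::write.csv(runs, paths["manifest"], row.names = FALSE)
  ind <- do.call(rbind, lapply(names(results), function(id) {
    x <- results[[id]]$indicators
    cbind(run_id = id, x)
  }))
  utils::write.csv(ind, paths["indicators"], row.names = FALSE)
  sens <- tryCatch(sensitivity_table(results, runs), error = function(e) NULL)
  if (!is.null(sens))
    utils::write.csv(sens, paths["sensitivity"], row.names = FALSE)
  invisible(paths)
}
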