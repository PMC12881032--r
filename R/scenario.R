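# Scenario worlds and deterministic transient driver series.
#
# Two internally consistent mid-century futures are encoded: a "positive"
# world of improving trends (median sea-level rise, maintained embankments,
# crop improvement, higher economic growth) and a "negative" world of
# deteriorating trends (high-end sea-level rise, declining embankments, no
# farm improvement, low growth, outmigration). All driver series are pure
# functions of the configuration so that the headline scenario parameters
# can be recovered exactly from the generated series.

.world_defs <- function() {
  list(
    positive = list(
      name = "positive",
      slr_midcentury_cm = 38.5,
      temp_rise_C = c(annual = 1.8, monsoon = 1.5, dry = 2.2),
      precip_change_frac = c(annual = -0.22, monsoon = -0.19, dry = -0.53),
      cyclone_rate_strong_per_decade = 0.4,
      cyclone_rate_weak_per_decade = 4.2,
      population_start_millions = 14,
      population_2050_millions = 14,
      embankment_rate_cm_per_yr = 0,
      unit_production_multiplier_midcentury = 1.2,
      rice_salt_tolerance_start_dS_m = 6,
      rice_salt_tolerance_end_dS_m = 13,
      econ_growth_per_yr = 0.025,
      cropland_share_midcentury = 1.0
    ),
    negative = list(
      name = "negative",
      slr_midcentury_cm = 73.5,
      temp_rise_C = c(annual = 1.9, monsoon = 1.5, dry = 2.5),
      precip_change_frac = c(annual = -0.04, monsoon = -0.02, dry = -0.16),
      cyclone_rate_strong_per_decade = 0.4,
      cyclone_rate_weak_per_decade = 4.2,
      population_start_millions = 14,
      population_2050_millions = 11,
      embankment_rate_cm_per_yr = -3,
      unit_production_multiplier_midcentury = 1.0,
      rice_salt_tolerance_start_dS_m = 6,
      rice_salt_tolerance_end_dS_m = 6,
      econ_growth_per_yr = 0.006,
      cropland_share_midcentury = 0.85
    )
  )
}

#' Validate a world configuration
#' @param config a list of scenario parameters (see [load_world()])
#' @return the config, invisibly, after checking invariants
#' @keywords internal
validate_world <- function(config) {
  stopifnot(is.list(config))
  req <- c("name", "slr_midcentury_cm", "temp_rise_C", "precip_change_frac",
           "cyclone_rate_strong_per_decade", "cyclone_rate_weak_per_decade",
           "population_start_millions", "population_2050_millions",
           "embankment_rate_cm_per_yr", "unit_production_multiplier_midcentury",
           "rice_salt_tolerance_start_dS_m", "rice_salt_tolerance_end_dS_m",
           "econ_growth_per_yr")
  miss <- setdiff(req, names(config))
  if (length(miss) > 0)
    stop("world config is missing fields: ", paste(miss, collapse = ", "))
  if (config$cyclone_rate_strong_per_decade < 0 ||
      config$cyclone_rate_weak_per_decade < 0)
    stop("cyclone rates must be non-negative")
  if (config$rice_salt_tolerance_start_dS_m < 0 ||
      config$rice_salt_tolerance_end_dS_m < config$rice_salt_tolerance_start_dS_m)
    stop("rice salt tolerance must satisfy 0 <= start <= end")
  if (config$population_start_millions <= 0 || config$population_2050_millions <= 0)
    stop("populations must be positive")
  if (config$econ_growth_per_yr < 0)
    stop("economic growth must be non-negative")
  invisible(config)
}

#' Load a named scenario world
#'
#' Returns the full mid-century parameter bundle for one of the two
#' built-in scenario worlds. The base period is 2000-2015 and the
#' mid-century window is 2040-2055; sea level is expressed relative to the
#' year 2000.
#'
#' @param name "positive" or "negative"
#' @return an object of class `world_config` (a named list of parameters)
#' @examples
#' load_world("positive")$slr_midcentury_cm # 38.5
#' @export
load_world <- function(name) {
  defs <- .world_defs()
  if (!is.character(name) || length(name) != 1 || !(name %in% names(defs)))
    stop("unknown world '", paste(name, collapse = ","),
         "'; valid options: ", paste(names(defs), collapse = ", "))
  config <- defs[[name]]
  validate_world(config)
  structure(config, class = "world_config")
}

#' @export
print.world_config <- function(x, ...) {
  cat("<world_config>", x$name, "\n")
  cat("  SLR mid-century:", x$slr_midcentury_cm, "cm;",
      "dT:", x$temp_rise_C[["annual"]], "C;",
      "dP:", 100 * x$precip_change_frac[["annual"]], "%\n")
  cat("  population:", x$population_start_millions, "->",
      x$population_2050_millions, "M;",
      "growth:", 100 * x$econ_growth_per_yr, "%/yr;",
      "embankment:", x$embankment_rate_cm_per_yr, "cm/yr\n")
  invisible(x)
}

#' Annual relative sea-level series
#'
#' Quadratic rise anchored at 0 cm in the year 2000, scaled so that the
#' 2040-2055 mean equals the configured mid-century value. Years before
#' 2000 are held at 0.
#'
#' @param config a `world_config`
#' @param years integer years covered (default 1985:2055)
#' @return data.frame with columns `year` and `slr_cm`
#' @export
slr_series <- function(config, years = 1985:2055) {
  validate_world(config)
  t <- pmax(0, years - 2000)
  a <- config$slr_midcentury_cm / mean((2040:2055 - 2000)^2)
  data.frame(year = years, slr_cm = a * t^2)
}

#' Annual population series (millions)
#'
#' Held at the start value until 2015, linear to the 2050 value, constant
#' afterwards.
#'
#' @inheritParams slr_series
#' @return data.frame with columns `year` and `population_millions`
#' @export
population_series <- function(config, years = 1985:2055) {
  validate_world(config)
  p0 <- config$population_start_millions
  p1 <- config$population_2050_millions
  frac <- pmin(1, pmax(0, (years - 2015) / (2050 - 2015)))
  data.frame(year = years, population_millions = p0 + frac * (p1 - p0))
}

#' Annual embankment height series (cm)
#'
#' Heights change by the configured signed rate per year from the first
#' year of the span and are floored at zero.
#'
#' @param initial_height_cm positive initial embankment height
#' @inheritParams slr_series
#' @return data.frame with columns `year` and `height_cm`
#' @export
embankment_series <- function(initial_height_cm, config, years = 2015:2050) {
  validate_world(config)
  if (initial_height_cm <= 0) stop("initial embankment height must be > 0")
  h <- initial_height_cm + config$embankment_rate_cm_per_yr * (years - years[1])
  data.frame(year = years, height_cm = pmax(0, h))
}

#' Annual economic index series
#'
#' Compound growth at the configured rate, equal to 1 in the base year.
#'
#' @param config a `world_config`
#' @param base_year year at which the index is 1
#' @param years integer years covered
#' @return data.frame with columns `year` and `econ_index`
#' @export
econ_index <- function(config, base_year = 2015, years = 1985:2055) {
  validate_world(config)
  data.frame(year = years,
             econ_index = (1 + config$econ_growth_per_yr)^(years - base_year))
}

#' Rice salinity tolerance for a given year (dS/m)
#'
#' Linear ramp from the start tolerance in 2015 to the end tolerance in
#' 2050 (the analysis window); clamped outside the ramp.
#'
#' @param config a `world_config`
#' @param year numeric year (vectorised)
#' @return tolerance in dS/m
#' @export
rice_tolerance <- function(config, year) {
  validate_world(config)
  frac <- pmin(1, pmax(0, (year - 2015) / (2050 - 2015)))
  config$rice_salt_tolerance_start_dS_m +
    frac * (config$rice_salt_tolerance_end_dS_m -
              config$rice_salt_tolerance_start_dS_m)
}

#' Crop unit-production multiplier for a given year
#'
#' Linear ramp from 1 in 2015 to the configured mid-century multiplier in
#' 2050; clamped outside the ramp.
#'
#' @inheritParams rice_tolerance
#' @return dimensionless multiplier
#' @export
unit_production_multiplier <- function(config, year) {
  validate_world(config)
  frac <- pmin(1, pmax(0, (year - 2015) / (2050 - 2015)))
  1 + frac * (config$unit_production_multiplier_midcentury - 1)
}

#' Cropland share of usable land for a given year
#'
#' Land-cover change is represented as a share-shift: the fraction of
#' non-mangrove land under crops ramps linearly from 1 in 2015 to the
#' configured mid-century share.
#'
#' @inheritParams rice_tolerance
#' @return fraction in (0, 1]
#' @export
cropland_share <- function(config, year) {
  validate_world(config)
  target <- config$cropland_share_midcentury %||% 1
  frac <- pmin(1, pmax(0, (year - 2015) / (2050 - 2015)))
  1 + frac * (target - 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
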