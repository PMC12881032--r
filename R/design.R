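# Experiment design: the 62-run sensitivity ensemble.
#
# 36 base scenarios (2 worlds x 3 cyclone sequences x 3 socio-economic
# variants x 2 sea-level levels) plus 26 one-at-a-time (OAT) runs, 13 per
# world: climate (no-climate-change), SLR (the other world's level),
# cyclones (x0.5 and x1.5), polder maintenance (the other regime), and for
# each of population / economy / land cover / farming the two of
# {More sustainable, Business as Usual, Less sustainable} not equal to the
# parent world's own level. Each OAT run differs from its parent world in
# exactly one driver.

SOCIO_DRIVERS <- c("population", "economy", "land cover", "farming")
SOCIO_LEVELS <- c("More sustainable", "Business as Usual", "Less sustainable")

# level tables for the three-level socio-economic drivers
.socio_level_value <- function(driver, level) {
  switch(driver,
    "population" = switch(level,
      "More sustainable" = 14, "Business as Usual" = 12.5,
      "Less sustainable" = 11),
    "economy" = switch(level,
      "More sustainable" = 0.025, "Business as Usual" = 0.0155,
      "Less sustainable" = 0.006),
    "farming" = switch(level,
      "More sustainable" = list(mult = 1.2, tol_end = 13),
      "Business as Usual" = list(mult = 1.1, tol_end = 9.5),
      "Less sustainable" = list(mult = 1.0, tol_end = 6)),
    "land cover" = switch(level,
      "More sustainable" = 1.0, "Business as Usual" = 0.925,
      "Less sustainable" = 0.85),
    stop("unknown socio driver ", driver))
}

.parent_socio_level <- function(world) {
  if (world == "positive") "More sustainable" else "Less sustainable"
}

.apply_socio <- function(config, driver, level) {
  v <- .socio_level_value(driver, level)
  switch(driver,
    "population" = { config$population_2050_millions <- v },
    "economy" = { config$econ_growth_per_yr <- v },
    "farming" = {
      config$unit_production_multiplier_midcentury <- v$mult
      config$rice_salt_tolerance_end_dS_m <- v$tol_end
    },
    "land cover" = { config$cropland_share_midcentury <- v })
  config
}

#' Enumerate the full 62-run sensitivity experiment design
#'
#' @param master_seed small integer; per-run seeds are derived from it
#' @return data.frame with one row per run: `run_id`, `parent_world`,
#'   `overridden_driver` ("none" for base scenarios), `override_level`,
#'   `slr_level`, `cyclone_seq`, `socio_variant`, `seed`
#' @export
enumerate_runs <- function(master_seed = 1) {
  rows <- list()
  add <- function(world, driver, level, slr_level, cyc_seq, socio) {
    rows[[length(rows) + 1L]] <<- data.frame(
      parent_world = world, overridden_driver = driver,
      override_level = level, slr_level = slr_level,
      cyclone_seq = cyc_seq, socio_variant = socio,
      stringsAsFactors = FALSE)
  }
  for (world in c("positive", "negative")) {
    own_slr <- if (world == "positive") "low" else "high"
    own_socio <- .parent_socio_level(world)
    # 18 base scenarios per world
    for (slr in c("low", "high"))
      for (cyc in 1:3)
        for (socio in SOCIO_LEVELS)
          add(world, "none", "", slr, cyc, socio)
    # 13 OAT runs per world (parent settings except the overridden driver)
    add(world, "climate", "no climate change", own_slr, 1L, own_socio)
    add(world, "SLR", if (own_slr == "low") "high" else "low",
        own_slr, 1L, own_socio)
    add(world, "cyclones", "-50%", own_slr, 1L, own_socio)
    add(world, "cyclones", "+50%", own_slr, 1L, own_socio)
    add(world, "polder",
        if (world == "positive") "declining" else "maintained",
        own_slr, 1L, own_socio)
    for (driver in SOCIO_DRIVERS)
      for (level in setdiff(SOCIO_LEVELS, own_socio))
        add(world, driver, level, own_slr, 1L, own_socio)
  }
  runs <- do.call(rbind, rows)
  runs$run_id <- sprintf("run%02d", seq_len(nrow(runs)))
  runs$seed <- as.integer(master_seed * 1000L + seq_len(nrow(runs)))
  runs[, c("run_id", "parent_world", "overridden_driver", "override_level",
           "slr_level", "cyclone_seq", "socio_variant", "seed")]
}

#' Build the effective scenario configuration for one run
#'
#' Applies the run's base-scenario variant (SLR level, socio-economic
#' variant) and, for OAT runs, its single driver override to the parent
#' world configuration. Returns the modified `world_config` together with
#' run-level switches that are not world parameters (cyclone frequency
#' multiplier, climate-change on/off, cyclone sequence seed).
#'
#' @param run one row of [enumerate_runs()] (data.frame or list)
#' @param master_seed the master seed used to derive sub-stream seeds
#' @return list with elements `config` (world_config),
#'   `cyclone_multiplier`, `climate_change` (logical), `cyclone_seed`,
#'   `seed`
#' @export
build_run_config <- function(run, master_seed = 1) {
  config <- load_world(run$parent_world)
  # base-scenario variant: SLR level and joint socio-economic variant
  config$slr_midcentury_cm <- if (run$slr_level == "low") 38.5 else 73.5
  if (run$overridden_driver == "none" || run$overridden_driver %in% SOCIO_DRIVERS) {
    socio_base <- run$socio_variant
    for (driver in SOCIO_DRIVERS)
      config <- .apply_socio(config, driver, socio_base)
  }
  cyclone_multiplier <- 1
  climate_change <- TRUE
  drv <- run$overridden_driver
  if (drv == "climate") {
    climate_change <- FALSE
  } else if (drv == "SLR") {
    config$slr_midcentury_cm <- if (run$override_level == "low") 38.5 else 73.5
  } else if (drv == "cyclones") {
    cyclone_multiplier <- if (run$override_level == "+50%") 1.5 else 0.5
  } else if (drv == "polder") {
    config$embankment_rate_cm_per_yr <-
      if (run$override_level == "maintained") 0 else -3
  } else if (drv %in% SOCIO_DRIVERS) {
    config <- .apply_socio(config, drv, run$override_level)
  } else if (drv != "none") {
    stop("unknown overridden driver '", drv, "' in run ", run$run_id)
  }
  if (!climate_change) {
    # "climate" covers precipitation, temperature and river discharge;
    # SLR is a separate driver and keeps its level
    config$temp_rise_C[] <- 0
    config$precip_change_frac[] <- 0
  }
  validate_world(config)
  list(config = config,
       cyclone_multiplier = cyclone_multiplier,
       climate_change = climate_change,
       cyclone_seed = as.integer(master_seed * 1000L + 900L + run$cyclone_seq),
       seed = run$seed)
}
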