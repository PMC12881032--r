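# Sensitivity ensemble, driver ranges and poverty attribution.

#' Run an ensemble of simulations
#'
#' @param runs rows of [enumerate_runs()] (all 62, or a subset)
#' @param region,archetypes,climatology synthetic inputs
#' @param master_seed master seed
#' @param years simulated years
#' @param sim [sim_config()]
#' @param verbose print per-run timing
#' @return named list of [simulate_run()] results, keyed by `run_id`
#' @export
run_ensemble <- function(runs, region, archetypes, climatology,
                         master_seed = 1, years = 1985:2050,
                         sim = sim_config(), verbose = FALSE) {
  res <- vector("list", nrow(runs))
  names(res) <- runs$run_id
  for (i in seq_len(nrow(runs))) {
    t0 <- proc.time()[["elapsed"]]
    r <- tryCatch(
      simulate_run(runs[i, ], region, archetypes, climatology,
                   master_seed, years, sim),
      error = function(e) stop("run ", runs$run_id[i], " failed: ",
                               conditionMessage(e)))
    res[[i]] <- r
    if (verbose)
      message(sprintf("%s [%s/%s %s] %.1fs", runs$run_id[i],
                      runs$parent_world[i], runs$overridden_driver[i],
                      runs$override_level[i],
                      proc.time()[["elapsed"]] - t0))
  }
  res
}

#' Sensitivity category of a percent change
#'
#' Low when the absolute change is at most 25%, high when at least 50%,
#' moderate in between.
#'
#' @param pct_change percent change (vectorised)
#' @return character: "low", "moderate" or "high"
#' @export
categorise <- function(pct_change) {
  stopifnot(all(is.finite(pct_change)))
  a <- abs(pct_change)
  ifelse(a <= 25, "low", ifelse(a >= 50, "high", "moderate"))
}

# percent change of an indicator's decadal mean against the 2005-2014
# baseline, for one run result
.run_change <- function(res, indicator, decade = c(2041, 2050)) {
  ind <- res$indicators
  base <- decadal_mean(ind[[indicator]], ind$year, c(2005, 2014))
  dec <- decadal_mean(ind[[indicator]], ind$year, decade)
  baseline_change(dec, base)$pct
}

# the canonical parent-world run of a world within a run table
.parent_run_id <- function(runs, world) {
  own_slr <- if (world == "positive") "low" else "high"
  own_socio <- if (world == "positive") "More sustainable" else "Less sustainable"
  id <- runs$run_id[runs$parent_world == world &
                      runs$overridden_driver == "none" &
                      runs$slr_level == own_slr & runs$cyclone_seq == 1 &
                      runs$socio_variant == own_socio]
  if (length(id) != 1) stop("no canonical parent run for world ", world)
  id
}

#' Sensitivity of one indicator to one driver in one world
#'
#' Collects the mid-century decadal changes (vs the 2005-2014 baseline)
#' across the driver's settings - the parent world plus its one-at-a-time
#' overrides - and reports their range (max - min).
#'
#' @param results [run_ensemble()] output
#' @param runs the run table the ensemble was built from
#' @param driver driver name (e.g. "SLR", "economy")
#' @param indicator indicator column name (e.g. "poverty_rate_pct")
#' @param world "positive" or "negative"
#' @param decade analysis decade (default 2041-2050)
#' @return list with `changes` (per setting), `range`, `category`
#' @export
driver_sensitivity <- function(results, runs, driver, indicator, world,
                               decade = c(2041, 2050)) {
  ids <- c(.parent_run_id(runs, world),
           runs$run_id[runs$parent_world == world &
                         runs$overridden_driver == driver])
  ids <- ids[ids %in% names(results)]
  if (length(ids) < 2)
    stop("driver '", driver, "' has fewer than 2 settings in this ensemble")
  changes <- vapply(results[ids], .run_change, numeric(1),
                    indicator = indicator, decade = decade)
  list(driver = driver, indicator = indicator, world = world,
       changes = changes, range = max(changes) - min(changes),
       category = categorise(max(abs(changes))))
}

#' Full sensitivity table across drivers and indicators
#'
#' Ranges are normalised per (indicator, world) by the largest range
#' across drivers, so exactly one driver attains 1 in each block.
#'
#' @inheritParams driver_sensitivity
#' @param drivers drivers to include
#' @param indicators indicator columns to include
#' @return data.frame with columns `world`, `driver`, `indicator`,
#'   `range`, `normalised`, `category`
#' @export
sensitivity_table <- function(results, runs,
                              drivers = c("climate", "SLR", "cyclones",
                                          "polder", "population", "economy",
                                          "land cover", "farming"),
                              indicators = c("inundated_area_km2",
                                             "soil_salinity_dS_m",
                                             "rice_production_t",
                                             "poverty_rate_pct", "gini",
                                             "gdp_per_capita"),
                              decade = c(2041, 2050)) {
  rows <- list()
  for (world in c("positive", "negative")) {
    if (!any(runs$parent_world == world)) next
    for (ind in indicators) {
      block <- lapply(drivers, function(drv)
        driver_sensitivity(results, runs, drv, ind, world, decade))
      ranges <- vapply(block, `[[`, numeric(1), "range")
      mx <- max(ranges)
      for (j in seq_along(block)) {
        rows[[length(rows) + 1L]] <- data.frame(
          world = world, driver = drivers[j], indicator = ind,
          range = ranges[j],
          normalised = if (mx > 0) ranges[j] / mx else 0,
          category = block[[j]]$category)
      }
    }
  }
  do.call(rbind, rows)
}

CLIMATIC_DRIVERS <- c("climate", "SLR", "cyclones")

#' Attribute poverty change to climatic versus non-climatic drivers
#'
#' For a household group, the climatic contribution is the mean absolute
#' mid-century decadal poverty-rate deviation of the climatic
#' one-at-a-time runs (climate, SLR, cyclones) from the parent world,
#' divided by the total decadal poverty change of the parent world
#' against the 2005-2014 baseline, clipped to \[0, 1\]; the non-climatic
#' share is one minus the climatic share. The extreme-year variant
#' replaces decadal means by the decade's maximum-poverty year.
#'
#' @inheritParams driver_sensitivity
#' @param group attribution group label (see [attribution_group()])
#' @return list with `group`, `climatic_share`, `nonclimatic_share`,
#'   `extreme_year_climatic_share` (shares are NA when the total change
#'   is zero)
#' @export
attribute_poverty <- function(results, runs, group, world = "positive",
                              decade = c(2041, 2050)) {
  parent <- results[[.parent_run_id(runs, world)]]
  oat_ids <- runs$run_id[runs$parent_world == world &
                           runs$overridden_driver %in% CLIMATIC_DRIVERS]
  oat_ids <- oat_ids[oat_ids %in% names(results)]
  if (length(oat_ids) == 0) stop("no climatic-driver runs in the ensemble")

  gseries <- function(res) {
    g <- res$group_poverty[res$group_poverty$group == group, ]
    if (nrow(g) == 0) stop("unknown household group '", group, "'")
    g
  }
  pg <- gseries(parent)
  dec_mean <- function(g) decadal_mean(g$poverty_rate_pct, g$year, decade)
  base <- decadal_mean(pg$poverty_rate_pct, pg$year, c(2005, 2014))

  share_of <- function(pick) {
    # pick maps a group series to the value used (decadal mean or
    # extreme year)
    p_val <- pick(pg)
    total <- abs(p_val - base)
    clim <- mean(vapply(results[oat_ids],
                        function(r) abs(pick(gseries(r)) - p_val),
                        numeric(1)))
    if (total == 0) return(NA_real_)
    min(1, clim / total)
  }
  dec_years <- seq(decade[1], decade[2])
  extreme_year <- {
    v <- pg$poverty_rate_pct[match(dec_years, pg$year)]
    dec_years[which.max(v)]
  }
  clim_share <- share_of(dec_mean)
  list(group = group, world = world,
       climatic_share = clim_share,
       nonclimatic_share = if (is.na(clim_share)) NA_real_ else 1 - clim_share,
       extreme_year_climatic_share = share_of(function(g)
         g$poverty_rate_pct[g$year == extreme_year]))
}
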