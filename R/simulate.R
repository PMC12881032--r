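# Integrated simulation of one scenario run: daily soil water-salt
# balance per union driven by the generated climate and flood events,
# seasonal crop yields with water / salt / temperature / flood limitation,
# and a monthly household microsimulation with coping, aggregated to
# annual headline indicators.

#' Simulation configuration
#' @param ... overrides of the defaults
#' @return named list of coupling constants: initial embankment height,
#'   sub-model parameter sets, cropping shares, prices and shock sizes
#' @export
sim_config <- function(...) {
  p <- list(
    initial_embankment_cm = 150,
    flood = flood_params(),
    soil = soil_params(),
    hh = household_config(),
    crops = default_crops(),
    mangrove_share = 0.1,       # forest share of area, excluded from cropping
    aman_area_frac = 0.7,       # cropland fraction under the monsoon crop
    boro_area_frac = 0.4,       # dry-season crop fraction, single-season
    boro_area_frac_multi = 0.8, # ... once multi-season cropping unlocks
    multi_season_ws_threshold = 0.75,
    rice_price_per_t = 15000,
    aqua_value_frac = 0.25,     # aquaculture value on top of rice value
    irrigation_factor = 1.1,    # irrigation demand multiplier on crop ET
    irrigation_base_ec = 1.0,
    irrigation_slr_ec = 4.0,    # extra irrigation EC per m of SLR at coast
    capillary_decay_distance = 0.5,
    asset_damage_strong = 0.25,
    asset_damage_weak = 0.08,
    flood_decay_per_day = 0.65, # standing flood water retreat factor
    bare_soil_coeff = 0.5,      # soil evaporation fraction of ET0 off-season
    mean_household_members = 4.5
  )
  over <- list(...)
  p[names(over)] <- over
  p
}

# daily schedules on the 365-day calendar: crop coefficient, root depth
# and season id (0 none, 1 aman, 2 boro)
.daily_schedules <- function(crops, soil) {
  kc <- rep(0, 365); season_id <- rep(0L, 365); root <- rep(0.3, 365)
  for (i in seq_len(nrow(crops))) {
    cal <- crop_calendar(crops[i, ])
    kc[cal$doy] <- cal$kc
    season_id[cal$doy] <- i
    nd <- nrow(cal)
    root[cal$doy] <- 0.15 + (soil$root_zone_max_m - 0.15) *
      pmin(1, cal$day_index / (0.6 * nd))
  }
  list(kc = kc, season_id = season_id, root = root)
}

#' Simulate one run of the integrated model
#'
#' @param run one row of [enumerate_runs()]
#' @param region union-cell table ([make_region()])
#' @param archetypes household archetype table ([make_archetypes()])
#' @param climatology baseline daily climatology ([make_climatology()])
#' @param master_seed master seed from which sub-stream seeds derive
#' @param years simulated years (default 1985:2050; the first years act
#'   as spin-up)
#' @param sim [sim_config()]
#' @return list with `run` (the run spec row), `indicators` (annual
#'   data.frame: `year`, `inundated_area_km2`, `soil_salinity_dS_m`,
#'   `rice_production_t`, `poverty_rate_pct`, `gini`, `gdp_per_capita`,
#'   `hungry_rate_pct`) and `group_poverty` (annual poverty rate per
#'   attribution group)
#' @export
simulate_run <- function(run, region, archetypes, climatology,
                         master_seed = 1, years = 1985:2050,
                         sim = sim_config()) {
  rc <- build_run_config(run, master_seed)
  config <- rc$config
  ny <- length(years)

  ## driver series -------------------------------------------------------
  slr <- slr_series(config, years)$slr_cm
  pop <- population_series(config, years)$population_millions
  econ <- econ_index(config, 2015, years)$econ_index
  emb <- sim$initial_embankment_cm +
    config$embankment_rate_cm_per_yr * pmax(0, years - 2015)
  emb <- pmax(0, emb) / 100 # m
  climate <- generate_climate(config, climatology, years = years)
  cyclones <- generate_cyclones(config$cyclone_rate_strong_per_decade,
                                config$cyclone_rate_weak_per_decade,
                                years, seed = rc$cyclone_seed,
                                freq_multiplier = rc$cyclone_multiplier)
  ann_clim <- annual_climate(climate)

  ## static cell quantities ---------------------------------------------
  n <- nrow(region)
  soil_par <- sim$soil
  cells_base <- region
  cap_ec_base <- soil_par$capillary_salinity_dS_m *
    exp(-region$coast_distance / sim$capillary_decay_distance)
  irr_ec_coast <- exp(-region$coast_distance / sim$capillary_decay_distance)
  crop_land_km2 <- region$area_km2 * (1 - sim$mangrove_share)
  sched <- .daily_schedules(sim$crops, soil_par)
  temp_by_doy <- matrix(climate$temp_C, nrow = 365)
  precip_by_doy <- matrix(climate$precip_mm, nrow = 365)

  ## household state -----------------------------------------------------
  hh <- sim$hh
  n_arch <- nrow(archetypes)
  hh_sav <- archetypes$initial_savings
  hh_debt <- rep(0, n_arch)
  hh_assets <- archetypes$assets_value
  hh_arrears <- rep(0L, n_arch)
  needs <- archetypes$monthly_food_need + archetypes$monthly_nonfood_need
  food_need <- archetypes$monthly_food_need
  fixed <- archetypes$fixed_livelihood_costs
  upl <- hh$upper_poverty_line_pc * archetypes$members
  wt <- archetypes$weight
  groups <- attribution_group(archetypes)
  group_levels <- sort(unique(groups))
  assets_ref <- mean(archetypes$assets_value)

  ## accumulators --------------------------------------------------------
  out <- data.frame(year = years, inundated_area_km2 = NA_real_,
                    soil_salinity_dS_m = NA_real_,
                    rice_production_t = NA_real_,
                    poverty_rate_pct = NA_real_, gini = NA_real_,
                    gdp_per_capita = NA_real_, hungry_rate_pct = NA_real_)
  gp <- matrix(NA_real_, ny, length(group_levels),
               dimnames = list(NULL, group_levels))

  soil_state <- soil_init(n, soil_par)
  standing <- rep(0, n)       # standing flood depth (m)
  standing_ec <- rep(0, n)
  boro_frac <- sim$boro_area_frac
  ws_boro_prev <- 0.7         # region-mean boro water stress, previous year
  n_seasons <- nrow(sim$crops)
  month_doy <- MONTH_END      # households update at each month's end

  for (iy in seq_len(ny)) {
    y <- years[iy]
    slr_m <- slr[iy] / 100
    cells <- cells_base
    cells$embankment_height_m <- ifelse(cells$poldered, emb[iy], 0)
    ev_y <- cyclones[cyclones$year == y, , drop = FALSE]

    # annual maximum flood state (indicator + event water for the soil)
    fl <- simulate_flood(cells, slr[iy], ann_clim$discharge_index[iy],
                         ann_clim$precip_mm[iy], ev_y, sim$flood)
    out$inundated_area_km2[iy] <- fl$inundated_area_km2

    # per-event flood fields for standing-water input to the soil
    ev_depth <- list(); ev_ec <- list()
    if (nrow(ev_y) > 0) {
      for (k in seq_len(nrow(ev_y))) {
        fk <- simulate_flood(cells, slr[iy], 0, 0, ev_y[k, , drop = FALSE],
                             sim$flood)
        ev_depth[[k]] <- fk$cells$mean_depth_m
        ev_ec[[k]] <- fk$cells$floodwater_ec_dS_m
      }
    }

    cap_ec <- cap_ec_base * (1 + slr_m)
    irr_ec <- sim$irrigation_base_ec + sim$irrigation_slr_ec * slr_m * irr_ec_coast
    tol_y <- rice_tolerance(config, y)
    mult_y <- unit_production_multiplier(config, y)
    cl_share <- cropland_share(config, y)

    temp_d <- temp_by_doy[, iy]
    precip_d <- precip_by_doy[, iy]
    et0_d <- reference_et(temp_d, 1:365)

    # seasonal accumulators per cell
    eta_s <- matrix(0, n, n_seasons); etm_s <- matrix(0, n, n_seasons)
    ec_sum_s <- matrix(0, n, n_seasons); ec_n_s <- integer(n_seasons)
    flood_run <- matrix(0L, n, n_seasons); flood_run_max <- matrix(0L, n, n_seasons)
    ec_max_y <- rep(0, n); ec_sum_y <- rep(0, n)

    for (d in 1:365) {
      sid <- sched$season_id[d]
      kc_d <- sched$kc[d]
      et_dem <- if (sid > 0) kc_d * et0_d[d] else sim$bare_soil_coeff * et0_d[d]

      irr <- 0
      if (sid == 2L) { # dry-season crop is irrigated
        irr <- max(0, sim$irrigation_factor * et_dem - precip_d[d])
      }

      if (nrow(ev_y) > 0) {
        hit <- which(ev_y$doy == d)
        for (k in hit) {
          upd <- ev_depth[[k]] > standing
          standing[upd] <- ev_depth[[k]][upd]
          standing_ec[upd] <- ev_ec[[k]][upd]
        }
      }

      st <- step_soil_day(soil_state, soil_par,
                          precip_mm = precip_d[d], et_mm = et_dem,
                          irrigation_mm = irr, irrigation_ec = irr_ec,
                          flood_depth_m = standing, flood_ec = standing_ec,
                          capillary_ec = cap_ec,
                          root_depth_m = sched$root[d],
                          diagnostics = FALSE)
      soil_state <- st$state
      ec_d <- soil_state$salt / pmax(soil_state$water_mm, 1e-12)
      ec_max_y <- pmax(ec_max_y, ec_d)
      ec_sum_y <- ec_sum_y + ec_d

      if (sid > 0) {
        eta_s[, sid] <- eta_s[, sid] + st$et_actual
        etm_s[, sid] <- etm_s[, sid] + et_dem
        ec_sum_s[, sid] <- ec_sum_s[, sid] + ec_d
        ec_n_s[sid] <- ec_n_s[sid] + 1L
        exceed <- standing >= sim$crops$flood_kill_depth_m[sid]
        flood_run[, sid] <- ifelse(exceed, flood_run[, sid] + 1L, 0L)
        flood_run_max[, sid] <- pmax(flood_run_max[, sid], flood_run[, sid])
      }

      standing <- standing * sim$flood_decay_per_day
      standing[standing < 0.005] <- 0
    }

    # seasonal crop results
    rice_t <- 0
    for (sid in seq_len(n_seasons)) {
      crop <- sim$crops[sid, ]
      if (ec_n_s[sid] == 0) next
      etm <- pmax(etm_s[, sid], 1e-9)
      f_w <- pmin(1, pmax(0, 1 - crop$ky * (1 - pmin(eta_s[, sid], etm) / etm)))
      ec_mean <- ec_sum_s[, sid] / ec_n_s[sid]
      thr <- if (grepl("aman|boro", crop$name)) tol_y else crop$salt_threshold_dS_m
      f_s <- salt_stress_factor(ec_mean, thr, crop$salt_slope_per_dS_m)
      sd_doy <- which(sched$season_id == sid)
      f_t <- temp_stress_factor(temp_d[sd_doy],
                                c(crop$temp_min_C, crop$temp_opt_lo_C,
                                  crop$temp_opt_hi_C, crop$temp_max_C))
      f_f <- pmax(0, 1 - flood_run_max[, sid] / crop$flood_kill_days)
      yield <- crop$potential_yield_t_ha * mult_y * f_w * f_s * f_t * f_f
      frac <- if (sid == 2L) boro_frac else sim$aman_area_frac
      area <- crop_land_km2 * cl_share * frac
      rice_t <- rice_t + sum(yield * area * 100)
      if (sid == 2L) ws_boro_prev <- stats::weighted.mean(f_w, area)
    }
    out$rice_production_t[iy] <- rice_t
    out$soil_salinity_dS_m[iy] <- stats::weighted.mean(ec_max_y, region$area_km2)

    # multi-season cropping unlocks when dry-season water supply and crop
    # tolerance allow it
    boro_frac <- if (ws_boro_prev >= sim$multi_season_ws_threshold &&
                     tol_y > 6)
      sim$boro_area_frac_multi else sim$boro_area_frac

    ## households ---------------------------------------------------------
    cropland_ha <- sum(crop_land_km2 * cl_share) * 100
    farm_value_month <- rice_t * sim$rice_price_per_t *
      (1 + sim$aqua_value_frac) / cropland_ha / 12
    labour_demand <- cl_share * (sim$aman_area_frac + boro_frac) /
      (sim$aman_area_frac + sim$boro_area_frac)
    inc <- monthly_income(archetypes, farm_value_month, labour_demand,
                          fish_index = 1, forest_index = 1,
                          econ_index = econ[iy], config = hh)
    ev_month <- if (nrow(ev_y) > 0) month_of_doy(ev_y$doy) else integer()
    flood_pop_frac <- if (nrow(ev_y) > 0)
      stats::weighted.mean(fl$cells$inundated_fraction, region$population) else 0

    poor_m <- hung_m <- matrix(FALSE, n_arch, 12)
    inc_yr <- rep(0, n_arch)
    for (m in 1:12) {
      if (m %in% ev_month) { # cyclone asset shock, absolute damage amount
        cls <- ev_y$intensity_class[ev_month == m]
        dmg <- max(ifelse(cls == "strong", sim$asset_damage_strong,
                          sim$asset_damage_weak))
        shock <- dmg * flood_pop_frac * assets_ref
        hh_assets <- pmax(0, hh_assets - shock)
      }
      for (i in seq_len(n_arch)) {
        income_i <- inc$total[i]
        inc_yr[i] <- inc_yr[i] + income_i
        debt1 <- hh_debt[i] * (1 + hh$interest_per_month)
        repay_due <- hh$repay_frac * debt1
        if (income_i >= needs[i] + fixed[i] + repay_due) {
          # no stress: full expenditure, scheduled repayment, save the rest
          hh_sav[i] <- hh_sav[i] + income_i - needs[i] - fixed[i] - repay_due
          hh_debt[i] <- debt1 - repay_due
          hh_arrears[i] <- 0L
          E <- needs[i]
        } else {
          res <- optimise_coping(list(savings = hh_sav[i], debt = hh_debt[i],
                                      assets = hh_assets[i],
                                      months_in_arrears = hh_arrears[i]),
                                 income_i, needs[i], food_need[i], fixed[i],
                                 hh)
          hh_sav[i] <- res$state$savings; hh_debt[i] <- res$state$debt
          hh_assets[i] <- res$state$assets
          hh_arrears[i] <- res$state$months_in_arrears
          E <- res$achieved_expenditure
        }
        poor_m[i, m] <- E < upl[i]
        hung_m[i, m] <- E < food_need[i]
      }
    }
    poor_share <- colSums(poor_m * wt) / sum(wt)
    out$poverty_rate_pct[iy] <- 100 * mean(poor_share)
    out$hungry_rate_pct[iy] <- 100 * mean(colSums(hung_m * wt) / sum(wt))
    out$gini[iy] <- gini(inc_yr, wt)
    n_households <- pop[iy] * 1e6 / sim$mean_household_members
    out$gdp_per_capita[iy] <- gdp_per_capita(
      sum(inc_yr * wt) * n_households, pop[iy] * 1e6)
    for (g in group_levels) {
      sel <- groups == g
      gp[iy, g] <- 100 * mean(colSums(poor_m[sel, , drop = FALSE] *
                                        wt[sel]) / sum(wt[sel]))
    }
  }

  group_poverty <- data.frame(
    year = rep(years, length(group_levels)),
    group = rep(group_levels, each = ny),
    poverty_rate_pct = as.numeric(gp))
  list(run = run, indicators = out, group_poverty = group_poverty)
}
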