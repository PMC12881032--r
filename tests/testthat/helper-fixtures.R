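# Shared fixtures. Expensive objects (the calibrated income scale and the
# mini ensemble of integrated runs) are computed once per test session
# and cached.

.fx <- new.env(parent = emptyenv())

fx_region <- function() {
  if (is.null(.fx$region)) .fx$region <- make_region(seed = 1, n_unions = 16)
  .fx$region
}

fx_arch <- function() {
  if (is.null(.fx$arch)) .fx$arch <- make_archetypes(seed = 1)
  .fx$arch
}

fx_clim <- function() {
  if (is.null(.fx$clim)) .fx$clim <- make_climatology()
  .fx$clim
}

fx_runs <- function() {
  if (is.null(.fx$runs)) .fx$runs <- enumerate_runs(master_seed = 1)
  .fx$runs
}

# calibrated income scale for the default synthetic region
fx_scale <- function() {
  if (is.null(.fx$scale)) {
    cal <- calibrate_baseline(fx_region(), fx_arch(), fx_clim(),
                              years = 2013:2015)
    .fx$cal <- cal
    .fx$scale <- cal$income_scale
  }
  .fx$scale
}

fx_calibration <- function() {
  fx_scale()
  .fx$cal
}

fx_sim <- function() {
  sim_config(hh = household_config(income_scale = fx_scale()))
}

# mini ensemble: both world parents plus the Positive World's climatic
# one-at-a-time runs (climate, SLR, cyclones x2); years trimmed to the
# baseline-to-midcentury window
fx_ensemble_years <- 2002:2050

fx_ensemble <- function() {
  if (is.null(.fx$ens)) {
    runs <- fx_runs()
    ids <- c(
      runs$run_id[runs$parent_world == "positive" &
                    runs$overridden_driver == "none" & runs$slr_level == "low" &
                    runs$cyclone_seq == 1 &
                    runs$socio_variant == "More sustainable"],
      runs$run_id[runs$parent_world == "negative" &
                    runs$overridden_driver == "none" & runs$slr_level == "high" &
                    runs$cyclone_seq == 1 &
                    runs$socio_variant == "Less sustainable"],
      runs$run_id[runs$parent_world == "positive" &
                    runs$overridden_driver %in% c("climate", "SLR", "cyclones")])
    sub <- runs[runs$run_id %in% ids, ]
    .fx$ens <- run_ensemble(sub, fx_region(), fx_arch(), fx_clim(),
                            master_seed = 1, years = fx_ensemble_years,
                            sim = fx_sim())
  }
  .fx$ens
}

# a 100-point forcing sweep of the toy flood model with its emulator
# forcing summaries, used by the emulator adequacy checks
fx_flood_sweep <- function() {
  if (is.null(.fx$sweep)) {
    reg <- make_region(seed = 1, n_unions = 64)
    grid <- expand.grid(slr = seq(0, 80, length.out = 5),
                        dis = seq(0.5, 1.5, length.out = 4),
                        pre = seq(1500, 2600, length.out = 5))
    out <- t(apply(grid, 1, function(r) {
      f <- simulate_flood(reg, r[1], r[2], r[3])
      c(area = f$inundated_area_km2,
        depth = mean(f$cells$mean_depth_m),
        ec = mean(f$cells$floodwater_ec_dS_m))
    }))
    .fx$sweep <- list(region = reg, grid = grid,
                      X = flood_forcing_summaries(grid$slr, grid$dis, grid$pre),
                      Y = out)
  }
  .fx$sweep
}

# canonical parent-world run id within a run table
.parent_id_of <- function(runs, world) {
  own_slr <- if (world == "positive") "low" else "high"
  own_socio <- if (world == "positive") "More sustainable" else
    "Less sustainable"
  runs$run_id[runs$parent_world == world &
                runs$overridden_driver == "none" &
                runs$slr_level == own_slr & runs$cyclone_seq == 1 &
                runs$socio_variant == own_socio]
}

# brute-force coping oracle: plain nested loops over the discrete action
# grid with explicit lexicographic tuple comparison, independent of the
# package's filtering implementation
oracle_coping <- function(state, income, needs, food_need, fixed_costs,
                          config) {
  debt1 <- state$debt * (1 + config$interest_per_month)
  obligations <- fixed_costs + config$repay_frac * debt1
  caps <- c(s = max(0, state$savings - config$min_savings),
            a = config$asset_liquidation_frac * state$assets,
            l = max(0, config$loan_cap_months * needs - state$debt),
            r = config$reduce_cap_frac * needs)
  wage <- config$labour_wage * config$income_scale
  lev <- (0:config$levels) / config$levels
  best <- NULL; best_key <- NULL
  for (m in 0:config$max_labour) for (s in lev * caps["s"])
    for (a in lev * caps["a"]) for (l in lev * caps["l"])
      for (r in lev * caps["r"]) {
        E <- max(0, needs - r)
        if (income + m * wage + s + a + l < E + obligations - 1e-9) next
        tier <- if (E >= needs - 1e-9) 2 else if (E >= food_need - 1e-9) 1 else 0
        k <- (m > 0) + (s > 0) + (a > 0) + (l > 0) + (r > 0)
        key <- c(-tier, m, k, -E, l, a, s, 0, r)
        if (is.null(best_key) || .lex_less(key, best_key)) {
          best_key <- key
          best <- list(labour = m, savings_draw = unname(s),
                       asset_sale = unname(a), loan = unname(l),
                       reduce = unname(r), expenditure = E)
        }
      }
  best
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-9) return(TRUE)
    if (a[i] > b[i] + 1e-9) return(FALSE)
  }
  FALSE
}
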