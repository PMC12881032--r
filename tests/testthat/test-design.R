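test_that("the experiment design has 62 runs: 36 base + 26 one-at-a-time", {
  runs <- fx_runs()
  expect_equal(nrow(runs), 62)
  expect_equal(sum(runs$overridden_driver == "none"), 36)
  expect_equal(sum(runs$overridden_driver != "none"), 26)
  expect_equal(anyDuplicated(runs$run_id), 0)
  # 36 base = 2 worlds x 2 SLR x 3 cyclone sequences x 3 socio variants
  base <- runs[runs$overridden_driver == "none", ]
  expect_equal(nrow(unique(base[, c("parent_world", "slr_level",
                                    "cyclone_seq", "socio_variant")])), 36)
  # 13 OAT runs per world
  oat <- runs[runs$overridden_driver != "none", ]
  expect_equal(as.vector(table(oat$parent_world)), c(13, 13))
})

test_that("each OAT run differs from its parent world in exactly one driver", {
  runs <- fx_runs()
  oat <- runs[runs$overridden_driver != "none", ]
  fields <- function(rc) {
    c(unlist(rc$config[c("slr_midcentury_cm", "population_2050_millions",
                         "econ_growth_per_yr",
                         "unit_production_multiplier_midcentury",
                         "rice_salt_tolerance_end_dS_m",
                         "embankment_rate_cm_per_yr",
                         "cropland_share_midcentury")]),
      temp = rc$config$temp_rise_C[["annual"]],
      precip = rc$config$precip_change_frac[["annual"]],
      cyc = rc$cyclone_multiplier)
  }
  driver_fields <- list(
    climate = c("temp", "precip"), SLR = "slr_midcentury_cm",
    cyclones = "cyc", polder = "embankment_rate_cm_per_yr",
    population = "population_2050_millions", economy = "econ_growth_per_yr",
    farming = c("unit_production_multiplier_midcentury",
                "rice_salt_tolerance_end_dS_m"),
    "land cover" = "cropland_share_midcentury")
  for (i in seq_len(nrow(oat))) {
    run <- oat[i, ]
    parent <- runs[runs$parent_world == run$parent_world &
                     runs$overridden_driver == "none" &
                     runs$slr_level == run$slr_level &
                     runs$cyclone_seq == run$cyclone_seq &
                     runs$socio_variant == run$socio_variant, ][1, ]
    fo <- fields(build_run_config(run, 1))
    fp <- fields(build_run_config(parent, 1))
    changed <- names(fo)[abs(fo - fp) > 1e-12]
    allowed <- driver_fields[[run$overridden_driver]]
    expect_true(length(changed) >= 1, info = run$run_id)
    expect_true(all(changed %in% allowed),
                info = paste(run$run_id, paste(changed, collapse = ",")))
  }
})

test_that("common random numbers: a cyclone override shares the parent's
           non-cyclone series", {
  runs <- fx_runs()
  run_cyc <- runs[runs$parent_world == "positive" &
                    runs$overridden_driver == "cyclones" &
                    runs$override_level == "+50%", ]
  parent <- runs[runs$run_id == "run01", ]
  rc_o <- build_run_config(run_cyc, 1)
  rc_p <- build_run_config(parent, 1)
  expect_equal(rc_o$cyclone_multiplier, 1.5)
  expect_identical(rc_o$config, rc_p$config)
  expect_identical(rc_o$cyclone_seed, rc_p$cyclone_seed)
  # identical Poisson substream: x1.5 run keeps the same seed so counts
  # move with the multiplier, all else equal
  clim <- fx_clim()
  e1 <- econ_index(rc_p$config, 2015, 2000:2050)
  e2 <- econ_index(rc_o$config, 2015, 2000:2050)
  expect_identical(e1, e2)
})

test_that("duplicate run spec and seed give identical simulations", {
  runs <- fx_runs()
  run <- runs[runs$run_id == "run01", ]
  reg <- make_region(seed = 2, n_unions = 8)
  a <- simulate_run(run, reg, fx_arch(), fx_clim(), 1, years = 2004:2016,
                    sim = fx_sim())
  b <- simulate_run(run, reg, fx_arch(), fx_clim(), 1, years = 2004:2016,
                    sim = fx_sim())
  expect_identical(a$indicators, b$indicators)
  expect_identical(a$group_poverty, b$group_poverty)
})
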