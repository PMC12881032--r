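test_that("world configurations carry the scenario parameter bundles", {
  pw <- load_world("positive")
  nw <- load_world("negative")
  expect_equal(pw$slr_midcentury_cm, 38.5)
  expect_equal(nw$slr_midcentury_cm, 73.5)
  expect_equal(nw$population_2050_millions, 11)
  expect_equal(nw$embankment_rate_cm_per_yr, -3)
  expect_equal(pw$econ_growth_per_yr, 0.025)
  expect_equal(nw$econ_growth_per_yr, 0.006)
  expect_equal(pw$rice_salt_tolerance_end_dS_m, 13)
  expect_error(load_world("middle"), "positive, negative")
})

test_that("sea-level series anchor at 2000 and recover mid-century means", {
  for (w in c("positive", "negative")) {
    cfg <- load_world(w)
    s <- slr_series(cfg, 1985:2055)
    expect_equal(s$slr_cm[s$year == 2000], 0)
    expect_true(all(diff(s$slr_cm) >= 0))
    expect_equal(mean(s$slr_cm[s$year %in% 2040:2055]),
                 cfg$slr_midcentury_cm)
  }
  # negative-world sea level dominates the positive world from 2000 on
  sp <- slr_series(load_world("positive"), 2000:2055)$slr_cm
  sn <- slr_series(load_world("negative"), 2000:2055)$slr_cm
  expect_true(all(sn >= sp))
})

test_that("population, embankment, economy and tolerance ramps are exact", {
  pw <- load_world("positive")
  nw <- load_world("negative")
  p <- population_series(nw, 2000:2055)
  expect_equal(p$population_millions[p$year == 2015], 14)
  expect_equal(p$population_millions[p$year == 2050], 11)
  expect_true(all(diff(p$population_millions[p$year %in% 2015:2050]) < 0))
  expect_true(all(population_series(pw)$population_millions == 14))

  e <- embankment_series(200, nw, 2001:2050)
  expect_true(all(abs(diff(e$height_cm) - (-3)) < 1e-12))
  expect_equal(e$height_cm[e$year == 2050], 200 - 3 * 49)
  e50 <- embankment_series(200, nw, 2000:2050)
  expect_equal(e50$height_cm[e50$year == 2050], 50) # 200 - 3 x 50
  expect_true(all(embankment_series(150, pw, 2015:2050)$height_cm == 150))
  # floored at zero
  elow <- embankment_series(30, nw, 2000:2050)
  expect_true(all(elow$height_cm >= 0))

  g <- econ_index(pw, 2015, 2015:2050)
  expect_equal(g$econ_index[1], 1)
  expect_equal(g$econ_index[g$year == 2050], 1.025^35)
  expect_equal(econ_index(load_world("negative"), 2015,
                          2050)$econ_index, 1.006^35)
  zero <- load_world("positive"); zero$econ_growth_per_yr <- 0
  expect_true(all(econ_index(zero, 2015, 2000:2050)$econ_index == 1))

  expect_equal(rice_tolerance(pw, 2015), 6)
  expect_equal(rice_tolerance(pw, 2050), 13)
  expect_equal(rice_tolerance(pw, 2032.5), 9.5)
  expect_true(all(rice_tolerance(nw, 2015:2050) == 6))
})

test_that("climate generator recovers annual anomaly targets exactly", {
  clim <- make_climatology()
  for (w in c("positive", "negative")) {
    cfg <- load_world(w)
    cc <- generate_climate(cfg, clim, years = 1985:2055)
    ac <- annual_climate(cc)
    base <- ac$year %in% 2000:2015
    mid <- ac$year %in% 2040:2055
    expect_equal(mean(ac$temp_C[mid]) - mean(ac$temp_C[base]),
                 cfg$temp_rise_C[["annual"]], tolerance = 1e-10)
    expect_equal(mean(ac$precip_mm[mid]) / mean(ac$precip_mm[base]) - 1,
                 cfg$precip_change_frac[["annual"]], tolerance = 1e-10)
    expect_true(all(cc$precip_mm >= 0))
    expect_equal(nrow(cc), 71 * 365)
  }
})

test_that("a zero-anomaly configuration reproduces the climatology", {
  clim <- make_climatology()
  cfg <- load_world("positive")
  cfg$temp_rise_C[] <- 0
  cfg$precip_change_frac[] <- 0
  cc <- generate_climate(cfg, clim, years = 2000:2055)
  ac <- annual_climate(cc)
  expect_equal(mean(ac$temp_C[ac$year %in% 2040:2055]),
               mean(ac$temp_C[ac$year %in% 2000:2015]))
  expect_equal(sd(ac$precip_mm), 0)
})

test_that("climate generation is deterministic and noise needs a seed", {
  clim <- make_climatology()
  cfg <- load_world("positive")
  a <- generate_climate(cfg, clim, years = 2000:2010)
  b <- generate_climate(cfg, clim, years = 2000:2010)
  expect_identical(a, b)
  expect_error(generate_climate(cfg, clim, years = 2000:2001, noise = TRUE),
               "seed")
  n1 <- generate_climate(cfg, clim, seed = 3, years = 2000:2001, noise = TRUE)
  n2 <- generate_climate(cfg, clim, seed = 3, years = 2000:2001, noise = TRUE)
  expect_identical(n1, n2)
})
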