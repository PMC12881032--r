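test_that("sensitivity categories follow the 25/50 percent thresholds", {
  expect_equal(categorise(25), "low")
  expect_equal(categorise(-25), "low")
  expect_equal(categorise(30), "moderate")
  expect_equal(categorise(-49.9), "moderate")
  expect_equal(categorise(50), "high")
  expect_equal(categorise(-120), "high")
  expect_equal(categorise(c(0, 30, 60)), c("low", "moderate", "high"))
  expect_error(categorise(NaN), "finite")
})

test_that("driver ranges are max minus min across settings", {
  # synthetic results: three settings with changes +10, -5, +20 -> 25
  runs <- fx_runs()
  mk <- function(vals) {
    years <- 2002:2050
    v <- rep(10, length(years))
    v[years >= 2041] <- vals
    list(indicators = data.frame(year = years, x = v))
  }
  ids <- c(.pid <- runs$run_id[runs$run_id == "run01"],
           runs$run_id[runs$parent_world == "positive" &
                         runs$overridden_driver == "cyclones"])
  fake <- list(mk(11), mk(9.5), mk(12))
  names(fake) <- ids
  ds <- driver_sensitivity(fake, runs, "cyclones", "x", "positive")
  expect_equal(unname(ds$changes), c(10, -5, 20))
  expect_equal(ds$range, 25)
  expect_equal(ds$category, "low")
  # identical settings give zero range
  same <- list(mk(11), mk(11), mk(11)); names(same) <- ids
  expect_equal(driver_sensitivity(same, runs, "cyclones", "x",
                                  "positive")$range, 0)
  expect_error(driver_sensitivity(fake[1], runs, "cyclones", "x", "positive"),
               "fewer than 2")
})

test_that("normalisation gives exactly one driver a value of 1 per block", {
  ens <- fx_ensemble()
  runs <- fx_runs()
  runs <- runs[runs$parent_world == "positive", ]
  st <- sensitivity_table(ens, runs, drivers = c("climate", "SLR", "cyclones"),
                          indicators = c("inundated_area_km2",
                                         "poverty_rate_pct"))
  st <- st[st$world == "positive", ]
  expect_true(all(st$normalised >= 0 & st$normalised <= 1))
  for (ind in unique(st$indicator)) {
    block <- st[st$indicator == ind, ]
    expect_equal(sum(block$normalised == 1), 1)
    expect_equal(max(block$normalised), 1)
  }
  expect_true(all(st$category %in% c("low", "moderate", "high")))
})

test_that("poverty attribution shares sum to one per household group", {
  ens <- fx_ensemble()
  runs <- fx_runs()
  arch <- fx_arch()
  groups <- sort(unique(attribution_group(arch)))
  n_defined <- 0
  for (g in groups) {
    at <- attribute_poverty(ens, runs, g, world = "positive")
    if (!is.na(at$climatic_share)) {
      n_defined <- n_defined + 1
      expect_equal(at$climatic_share + at$nonclimatic_share, 1)
      expect_gte(at$climatic_share, 0)
      expect_lte(at$climatic_share, 1)
      if (!is.na(at$extreme_year_climatic_share)) {
        expect_gte(at$extreme_year_climatic_share, 0)
        expect_lte(at$extreme_year_climatic_share, 1)
      }
    }
  }
  expect_gte(n_defined, 1)
})

test_that("worked attribution example: climatic 2 of total 8 points", {
  # a parent decadal change of -8 poverty points of which the climatic
  # one-at-a-time deviation averages 2 points gives shares (0.25, 0.75)
  runs <- fx_runs()
  years <- 2002:2050
  mk <- function(base_level, late_level) {
    v <- rep(base_level, length(years))
    v[years >= 2041] <- late_level
    list(group_poverty = data.frame(year = years, group = "all",
                                    poverty_rate_pct = v))
  }
  parent_id <- "run01"
  clim_ids <- runs$run_id[runs$parent_world == "positive" &
                            runs$overridden_driver %in%
                              c("climate", "SLR", "cyclones")]
  fake <- c(list(mk(20, 12)), lapply(seq_along(clim_ids),
                                     function(i) mk(20, 14)))
  names(fake) <- c(parent_id, clim_ids)
  at <- attribute_poverty(fake, runs, "all", "positive")
  expect_equal(at$climatic_share, 0.25)
  expect_equal(at$nonclimatic_share, 0.75)
})
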