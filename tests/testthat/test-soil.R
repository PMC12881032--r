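test_that("a null step leaves the state unchanged", {
  p <- soil_params(capillary_rate_mm_day = 0)
  st <- soil_init(3, p, ec_dS_m = 6)
  out <- step_soil_day(st, p, precip_mm = 0, et_mm = 0)
  expect_equal(out$state$water_mm, st$water_mm)
  expect_equal(out$state$salt, st$salt)
})

test_that("the hand-worked day matches the arithmetic oracle", {
  # W = 100 mm at EC 6 (salt 600), irrigation 20 mm at EC 2, ET 5 mm,
  # drainage coefficient 0.1/day, field-capacity store 110 mm,
  # leaching efficiency 1, no capillary rise:
  #   W_in = 120, salt_in = 640, W1 = 115
  #   percolation = 0.1 x (115 - 110) = 0.5
  #   salt leached = 640 x 0.5/115 = 2.78261
  #   W' = 114.5, salt' = 637.21739, EC' = 5.56522
  p <- soil_params(drainage_coeff_per_day = 0.1, field_capacity = 0.22,
                   porosity = 0.45, leaching_efficiency = 1,
                   capillary_rate_mm_day = 0, wilting_point = 0.05)
  st <- list(water_mm = 100, salt = 600, root_depth_m = 0.5)
  out <- step_soil_day(st, p, precip_mm = 0, et_mm = 5,
                       irrigation_mm = 20, irrigation_ec = 2)
  expect_equal(out$state$water_mm, 114.5)
  expect_equal(out$state$salt, 640 - 640 * 0.5 / 115)
  expect_equal(soil_ec(out$state), (640 - 640 * 0.5 / 115) / 114.5)
})

test_that("water and salt mass balance closes to 1e-9 over random forcing", {
  set.seed(21)
  p <- soil_params()
  st <- soil_init(5, p, ec_dS_m = 5)
  for (d in 1:200) {
    precip <- rgamma(1, 0.7, scale = 12)
    et <- runif(1, 1, 7)
    irr <- ifelse(runif(1) < 0.3, runif(1, 0, 10), 0)
    fl <- ifelse(runif(1) < 0.05, runif(5, 0, 0.5), 0)
    rd <- runif(1, 0.2, 0.6)
    out <- step_soil_day(st, p, precip, et, irrigation_mm = irr,
                         irrigation_ec = 2, flood_depth_m = fl,
                         flood_ec = 18, root_depth_m = rd)
    fx <- out$fluxes
    dW <- out$state$water_mm - st$water_mm
    expect_true(all(abs(dW - (fx$precip + fx$irrigation +
                                fx$flood_infiltration + fx$capillary +
                                fx$root_in_w - fx$root_out_w - fx$et -
                                fx$percolation - fx$drainage)) < 1e-9))
    dS <- out$state$salt - st$salt
    expect_true(all(abs(dS - (fx$salt_in + fx$root_in_s - fx$root_out_s -
                                fx$salt_perc - fx$salt_drain)) < 1e-9))
    expect_true(all(out$state$water_mm >= 0))
    expect_true(all(out$state$water_mm <=
                      p$porosity * out$state$root_depth_m * 1000 + 1e-9))
    st <- out$state
  }
})

test_that("repeated fresh rain with percolation strictly lowers EC", {
  p <- soil_params(capillary_rate_mm_day = 0)
  st <- soil_init(1, p, ec_dS_m = 8)
  ecs <- soil_ec(st)
  for (d in 1:30) {
    st <- step_soil_day(st, p, precip_mm = 20, et_mm = 2)$state
    ecs <- c(ecs, soil_ec(st))
  }
  expect_true(all(diff(ecs) < 0))
})

test_that("saline flooding never lowers EC; dry-out never lowers EC", {
  p <- soil_params(capillary_rate_mm_day = 0)
  set.seed(4)
  for (i in 1:20) {
    ec0 <- runif(1, 1, 10)
    st <- soil_init(1, p, ec_dS_m = ec0)
    out <- step_soil_day(st, p, precip_mm = 0, et_mm = runif(1, 0, 4),
                         flood_depth_m = runif(1, 0.05, 1),
                         flood_ec = ec0 + runif(1, 0.5, 15))
    expect_gte(soil_ec(out$state), ec0 - 1e-12)
  }
  # zero inputs: water declines, EC non-decreasing
  st <- soil_init(1, p, ec_dS_m = 6)
  ecs <- soil_ec(st)
  for (d in 1:60) {
    st <- step_soil_day(st, p, precip_mm = 0, et_mm = 5)$state
    ecs <- c(ecs, soil_ec(st))
  }
  expect_true(all(diff(ecs) >= -1e-12))
})

test_that("ET demand above available water is capped and flagged", {
  p <- soil_params(capillary_rate_mm_day = 0, wilting_point = 0.1)
  st <- list(water_mm = 52, salt = 100, root_depth_m = 0.5)
  out <- step_soil_day(st, p, precip_mm = 0, et_mm = 10)
  expect_equal(out$fluxes$et, 2) # only water above the 50 mm wilting store
  expect_true(out$fluxes$et_capped)
})

test_that("a drier monsoon yields higher soil salinity than a wetter one", {
  clim <- fx_clim()
  p <- soil_params()
  run_ec <- function(scale) {
    st <- soil_init(1, p)
    cap_ec <- p$capillary_salinity_dS_m * exp(-0.3 / 0.5)
    ecs <- numeric(0)
    for (y in 1:6) for (d in 1:365) {
      et0 <- reference_et(clim$temp_C[d], d)
      st <- step_soil_day(st, p, precip_mm = clim$precip_mm[d] * scale,
                          et_mm = 0.7 * et0, capillary_ec = cap_ec,
                          diagnostics = FALSE)$state
      if (y == 6) ecs <- c(ecs, soil_ec(st))
    }
    mean(ecs)
  }
  expect_gt(run_ec(0.78), run_ec(0.96)) # -22% vs -4% precipitation
})

test_that("annual salinity statistics behave", {
  expect_equal(annual_salinity_stats(rep(6, 365)), c(max = 6, mean = 6))
  expect_equal(annual_salinity_stats(c(4, 8)), c(max = 8, mean = 6))
  s <- runif(100, 0, 12)
  st <- annual_salinity_stats(s)
  expect_gte(st[["max"]], st[["mean"]])
  expect_error(annual_salinity_stats(numeric(0)), "empty")
})
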