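test_that("monthly income scales linearly with its indices", {
  arch <- fx_arch()
  cfg <- household_config()
  zero <- monthly_income(arch, 0, 0, 0, 0, 0, cfg)
  expect_true(all(zero$total == 0))
  one <- monthly_income(arch, 500, 1, 1, 1, 1, cfg)
  two <- monthly_income(arch, 500, 1, 1, 1, 2, cfg)
  expect_equal(two$manufacturing, 2 * one$manufacturing)
  expect_equal(two$business, 2 * one$business)
  expect_equal(two$farming, one$farming)
  # landless households earn no own-farm income
  expect_true(all(one$farming[arch$land_ha == 0] == 0))
  # worked single-household ledger: 5 members, shares 0.45 farm labour /
  # 0.55 spread, land 0.4 ha
  h <- arch[arch$archetype_id == "farm_labour_small_mixed", ]
  inc <- monthly_income(h, 800, 0.5, 1, 1, 1.2, cfg)
  expect_equal(inc$farming, 0.4 * 800)
  expect_equal(inc$farm_labour,
               h$members * cfg$labour_wage * h$farm_labour * 0.5)
  expect_equal(inc$business, h$members * cfg$base_business * h$business * 1.2)
  expect_equal(inc$total, rowSums(inc[, 1:6]))
})

test_that("an unstressed month needs no coping plan", {
  cfg <- household_config()
  st <- list(savings = 5000, debt = 0, assets = 20000, months_in_arrears = 0L)
  res <- optimise_coping(st, income = 12000, needs = 8000, food_need = 4600,
                         fixed_costs = 500, cfg)
  expect_equal(res$plan$n_actions, 0L)
  expect_equal(res$achieved_expenditure, 8000)
  expect_equal(res$plan$labour, 0)
  expect_false(res$plan$deficit)
  expect_equal(res$state$savings, 5000 + 12000 - 8000 - 500)
})

test_that("fewer coping strategies are preferred when savings suffice", {
  cfg <- household_config()
  st <- list(savings = 10000, debt = 0, assets = 50000,
             months_in_arrears = 0L)
  # shortfall 2000: coverable by savings alone, or by loan + asset sale
  res <- optimise_coping(st, income = 6500, needs = 8000, food_need = 4600,
                         fixed_costs = 500, cfg)
  expect_equal(res$plan$n_actions, 1L)
  expect_gt(res$plan$savings_draw, 0)
  expect_equal(res$plan$loan, 0)
  expect_equal(res$plan$asset_sale, 0)
  expect_equal(res$achieved_expenditure, 8000)
})

test_that("the optimiser matches exhaustive enumeration on small instances", {
  set.seed(99)
  n_checked <- 0
  for (i in 1:120) {
    levels <- sample(2:5, 1)
    cfg <- household_config(levels = levels, max_labour = 0L,
                            transfer_cap_frac = 0)
    # three actions: savings draw, loan, expenditure cut (no assets,
    # no labour); debt-free so safety nets cannot alter the search
    st <- list(savings = round(runif(1, 0, 8000)), debt = 0,
               assets = 0, months_in_arrears = 0L)
    income <- round(runif(1, 0, 9000))
    needs <- round(runif(1, 4000, 9000))
    food <- round(0.6 * needs)
    fixed <- round(runif(1, 0, 1000))
    mine <- optimise_coping(st, income, needs, food, fixed, cfg)
    oracle <- oracle_coping(st, income, needs, food, fixed, cfg)
    if (is.null(oracle)) next
    n_checked <- n_checked + 1
    expect_equal(mine$plan$savings_draw, oracle$savings_draw, info = i)
    expect_equal(mine$plan$loan, oracle$loan, info = i)
    expect_equal(mine$plan$reduce, oracle$reduce, info = i)
    expect_equal(mine$achieved_expenditure, oracle$expenditure, info = i)
  }
  expect_gt(n_checked, 80)
})

test_that("the monthly ledger closes exactly", {
  set.seed(5)
  cfg <- household_config()
  st <- list(savings = 3000, debt = 4000, assets = 15000,
             months_in_arrears = 0L)
  for (i in 1:50) {
    income <- runif(1, 500, 12000)
    res <- optimise_coping(st, income, needs = 8000, food_need = 4600,
                           fixed_costs = 600, cfg)
    lg <- res$ledger
    repay <- lg[["repay"]]
    d_savings <- res$state$savings - st$savings
    expect_lt(abs(d_savings - (lg[["income"]] + lg[["labour"]] +
                                 lg[["asset_sale"]] + lg[["loan"]] +
                                 lg[["transfer"]] + lg[["unpaid"]] -
                                 lg[["expenditure"]] - lg[["fixed"]] -
                                 repay)), 1e-6)
    st <- res$state
  }
})

test_that("hardship is monotone: lower income never needs fewer actions", {
  cfg <- household_config()
  st <- list(savings = 2000, debt = 0, assets = 6000, months_in_arrears = 0L)
  incomes <- seq(9000, 500, by = -500)
  k <- sapply(incomes, function(inc)
    optimise_coping(st, inc, needs = 8000, food_need = 4600,
                    fixed_costs = 500, cfg)$plan$n_actions)
  expect_true(all(diff(k) >= 0))
})

test_that("identical absolute asset shocks hit the poorest hardest", {
  arch <- fx_arch()
  sh <- apply_asset_shock(arch$assets_value, arch$initial_savings, 8000)
  wealth <- arch$assets_value + arch$initial_savings
  ord <- order(wealth)
  expect_true(all(diff(sh$wealth_loss_frac[ord]) <= 1e-12))
  expect_true(all(sh$assets >= 0))
})

test_that("poverty and hunger use strict thresholds", {
  cl <- classify_poverty(c(8000, 7999, 0, 4600), 8000, 4600)
  expect_equal(cl$poor, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(cl$hungry, c(FALSE, FALSE, TRUE, FALSE))
})
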