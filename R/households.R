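# Household livelihoods: monthly income by occupation source, the
# coping-strategy optimiser and poverty classification.
#
# Each archetype earns from up to six sources: own farming (land share of
# the farm output value), farm wage labour (capped by regional labour
# demand), fishing and forest-goods collection (index-driven), and
# manufacturing / small business (scaled by the economic index). When a
# month's income cannot cover needs plus obligations, a coping plan is
# chosen from a discrete action space by lexicographic optimisation:
# meet as much of needs as possible, with as few labouring members as
# possible, then as few distinct coping actions as possible, then
# maximising the achieved expenditure; safety nets (postponed loan
# repayment, support from friends and family) apply only when coping
# actions are insufficient.

#' Household economy configuration
#' @param ... overrides of the defaults
#' @return named list of monetary constants: per-member base income rates
#'   (currency/month at full occupation share), the agricultural wage,
#'   coping caps and discretisation, interest and repayment rates
#' @export
household_config <- function(...) {
  p <- list(
    base_fishing = 6000, base_forest = 4000,
    base_manufacturing = 7000, base_business = 8000,
    labour_wage = 2500,           # per member-month of agricultural labour
    min_savings = 500,
    asset_liquidation_frac = 0.25, # sellable fraction of assets per month
    loan_cap_months = 2,           # loan ceiling in multiples of needs
    reduce_cap_frac = 0.4,         # largest voluntary expenditure cut
    transfer_cap_frac = 0.3,       # friends-and-family support ceiling
    levels = 5L,                   # nonzero grid levels per action
    max_labour = 2L,               # extra members available for labouring
    interest_per_month = 0.01,
    repay_frac = 0.05,             # monthly repayment share of debt
    upper_poverty_line_pc = 1800,  # currency per person-month
    income_scale = 1
  )
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Monthly household income by source
#'
#' @param arch archetype table ([make_archetypes()]); vectorised over rows
#' @param farm_value_per_ha monthly own-farm output value per hectare
#' @param labour_demand_ratio regional agricultural labour demand relative
#'   to full employment, capped at 1
#' @param fish_index,forest_index dimensionless source indices
#' @param econ_index economic index for off-farm sources
#' @param config [household_config()]
#' @return data.frame of per-source incomes and their `total`
#' @export
monthly_income <- function(arch, farm_value_per_ha, labour_demand_ratio,
                           fish_index = 1, forest_index = 1, econ_index = 1,
                           config = household_config()) {
  stopifnot(farm_value_per_ha >= 0, labour_demand_ratio >= 0,
            fish_index >= 0, forest_index >= 0, econ_index >= 0)
  demand <- min(1, labour_demand_ratio)
  inc <- data.frame(
    farming = ifelse(arch$farming > 0, arch$land_ha * farm_value_per_ha, 0),
    farm_labour = arch$members * config$labour_wage * arch$farm_labour * demand,
    fishing = arch$members * config$base_fishing * arch$fishing * fish_index,
    forest = arch$members * config$base_forest * arch$forest * forest_index,
    manufacturing = arch$members * config$base_manufacturing *
      arch$manufacturing * econ_index,
    business = arch$members * config$base_business * arch$business * econ_index
  )
  inc <- inc * config$income_scale
  inc$total <- rowSums(inc)
  inc
}

# action-level grids are cached: they depend only on the discretisation
.plan_grid_cache <- new.env(parent = emptyenv())
.plan_grid <- function(levels, max_labour, with_transfer) {
  key <- paste(levels, max_labour, with_transfer)
  g <- .plan_grid_cache[[key]]
  if (is.null(g)) {
    lev <- (0:levels) / levels
    g <- expand.grid(m = 0:max_labour, s = lev, a = lev, l = lev, r = lev,
                     tr = if (with_transfer) lev else 0)
    .plan_grid_cache[[key]] <- g
  }
  g
}

# Evaluate every plan on the discrete grid and return the best under the
# lexicographic objective. Internal; shared by the optimiser passes.
.best_plan <- function(income, needs, food_need, obligations, caps, levels,
                       max_labour, wage, transfer_cap = 0) {
  grid <- .plan_grid(levels, max_labour, transfer_cap > 0)
  s_draw <- grid$s * caps["savings"]
  a_sale <- grid$a * caps["assets"]
  loan <- grid$l * caps["loan"]
  reduce <- grid$r * caps["reduce"]
  transfer <- grid$tr * transfer_cap
  labour_inc <- grid$m * wage
  E <- pmax(0, needs - reduce)
  inflow <- income + labour_inc + s_draw + a_sale + loan + transfer
  idx <- which(inflow >= E + obligations - 1e-9)
  if (length(idx) == 0) return(NULL)
  tier <- ifelse(E >= needs - 1e-9, 2, ifelse(E >= food_need - 1e-9, 1, 0))
  k <- (grid$m > 0) + (s_draw > 0) + (a_sale > 0) + (loan > 0) + (reduce > 0)
  # lexicographic selection by successive filtering
  keep <- function(idx, v, best) idx[v[idx] == best]
  idx <- keep(idx, tier, max(tier[idx]))
  idx <- keep(idx, grid$m, min(grid$m[idx]))
  idx <- keep(idx, k, min(k[idx]))
  idx <- keep(idx, E, max(E[idx]))
  idx <- keep(idx, loan, min(loan[idx]))
  idx <- keep(idx, a_sale, min(a_sale[idx]))
  idx <- keep(idx, s_draw, min(s_draw[idx]))
  idx <- keep(idx, transfer, min(transfer[idx]))
  i <- idx[1]
  list(labour = grid$m[i], savings_draw = s_draw[i], asset_sale = a_sale[i],
       loan = loan[i], reduce = reduce[i], transfer = transfer[i],
       expenditure = E[i], tier = tier[i], n_actions = k[i])
}

#' Optimise a household's monthly coping plan
#'
#' Chooses amounts for the coping actions (cash savings, asset sale,
#' loan, expenditure reduction, temporary agricultural labouring) on a
#' discrete grid (`levels` nonzero steps per action up to each cap). The
#' objective is lexicographic: first achieve the highest attainable tier
#' (full needs met > food need met > neither), then the fewest labouring
#' members, then the fewest distinct coping actions, then the highest
#' achieved expenditure; remaining ties prefer avoiding loans, then asset
#' sales, then savings draws. Safety nets (postponing the loan repayment,
#' then a transfer from friends and family) are tried only when coping
#' actions cannot meet full needs.
#'
#' @param state list with `savings`, `debt`, `assets`,
#'   `months_in_arrears`
#' @param income total monthly income (currency)
#' @param needs monthly food + non-food needs (currency)
#' @param food_need monthly food need (currency)
#' @param fixed_costs fixed livelihood costs (currency/month)
#' @param config [household_config()]
#' @return list with `plan` (chosen amounts, safety-net flags, `deficit`
#'   flag), the updated `state`, `achieved_expenditure`, and `ledger`
#'   (all cash flows of the month)
#' @export
optimise_coping <- function(state, income, needs, food_need,
                            fixed_costs = 0, config = household_config()) {
  debt1 <- state$debt * (1 + config$interest_per_month)
  repayment_due <- config$repay_frac * debt1
  caps <- c(savings = max(0, state$savings - config$min_savings),
            assets = config$asset_liquidation_frac * state$assets,
            # the loan cap is a ceiling on outstanding debt
            loan = max(0, config$loan_cap_months * needs - state$debt),
            reduce = config$reduce_cap_frac * needs)
  wage <- config$labour_wage * config$income_scale

  postponed <- FALSE
  transfer_cap <- 0
  plan <- .best_plan(income, needs, food_need, fixed_costs + repayment_due,
                     caps, config$levels, config$max_labour, wage)
  if (is.null(plan) || plan$tier < 2) {
    # safety net 1: postpone the loan repayment
    p2 <- .best_plan(income, needs, food_need, fixed_costs,
                     caps, config$levels, config$max_labour, wage)
    if (!is.null(p2) && (is.null(plan) || p2$tier > plan$tier ||
                         (p2$tier == plan$tier && p2$expenditure >
                            plan$expenditure + 1e-9))) {
      plan <- p2; postponed <- TRUE
    }
  }
  if (is.null(plan) || plan$tier < 2) {
    # safety net 2: support from friends and family
    transfer_cap <- config$transfer_cap_frac * needs
    p3 <- .best_plan(income, needs, food_need, fixed_costs,
                     caps, config$levels, config$max_labour, wage,
                     transfer_cap = transfer_cap)
    if (!is.null(p3) && (is.null(plan) || p3$tier > plan$tier ||
                         (p3$tier == plan$tier && p3$expenditure >
                            plan$expenditure + 1e-9))) {
      plan <- p3; postponed <- TRUE
    }
  }

  deficit <- FALSE
  unpaid <- 0
  if (is.null(plan)) {
    # distress: all actions at cap, repayment postponed, expenditure
    # floored at what remains after fixed costs
    deficit <- TRUE; postponed <- TRUE
    inflow <- income + config$max_labour * wage + caps[["assets"]] +
      caps[["loan"]] + config$transfer_cap_frac * needs
    avail <- state$savings + inflow - fixed_costs
    E <- max(0, min(needs, avail))
    unpaid <- max(0, fixed_costs - (state$savings + inflow))
    plan <- list(labour = config$max_labour,
                 savings_draw = max(0, state$savings - max(0, avail - E)),
                 asset_sale = caps[["assets"]], loan = caps[["loan"]],
                 reduce = needs - E, transfer = config$transfer_cap_frac * needs,
                 expenditure = E, tier = 0, n_actions = 5L)
  }

  repay <- if (postponed) 0 else min(repayment_due, debt1)
  new_state <- list(
    savings = state$savings + income + plan$labour * wage + plan$asset_sale +
      plan$loan + plan$transfer - plan$expenditure - fixed_costs - repay +
      unpaid,
    debt = debt1 + plan$loan - repay,
    assets = state$assets - plan$asset_sale,
    months_in_arrears = if (postponed) state$months_in_arrears + 1L else 0L
  )
  new_state$savings <- max(0, new_state$savings)
  plan$postponed_repayment <- postponed
  plan$deficit <- deficit
  list(plan = plan, state = new_state,
       achieved_expenditure = plan$expenditure,
       ledger = c(income = income, labour = plan$labour * wage,
                  asset_sale = plan$asset_sale, loan = plan$loan,
                  transfer = plan$transfer, expenditure = plan$expenditure,
                  fixed = fixed_costs, repay = repay, unpaid = unpaid))
}

#' Poverty and hunger flags
#'
#' A household is poor in a month when its achieved expenditure falls
#' strictly below the upper poverty line (cost of basic food and
#' non-food needs), and hungry when the achievable food expenditure falls
#' below the food need.
#'
#' @param achieved_expenditure achieved monthly expenditure (vectorised)
#' @param poverty_line household-level upper poverty line (per-capita line
#'   times members)
#' @param food_need household monthly food need
#' @return data.frame with logical columns `poor` and `hungry`
#' @export
classify_poverty <- function(achieved_expenditure, poverty_line, food_need) {
  stopifnot(all(poverty_line > 0))
  data.frame(poor = achieved_expenditure < poverty_line,
             hungry = achieved_expenditure < food_need)
}
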