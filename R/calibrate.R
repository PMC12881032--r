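# Baseline calibration: a uniform income scaling is found by bisection so
# that the simulated 2015 rural poverty rate matches a target (default
# 27%), preserving the expenditure structure (needs are never scaled).

#' Calibrate baseline incomes to a target poverty rate
#'
#' @param region,archetypes,climatology synthetic inputs
#' @param target_poverty_pct target 2015 poverty rate (percent, in
#'   (0, 100))
#' @param tolerance acceptable deviation (percentage points)
#' @param bounds search interval for the income scale
#' @param years short simulation window ending in 2015 used for the
#'   evaluation
#' @param sim [sim_config()]
#' @param master_seed master seed
#' @param max_iter bisection iterations
#' @return list with `income_scale`, `achieved_poverty_pct`,
#'   `iterations` and a `report` data.frame of the bisection trace
#' @export
calibrate_baseline <- function(region, archetypes, climatology,
                               target_poverty_pct = 27, tolerance = 2,
                               bounds = c(0.2, 5), years = 2012:2015,
                               sim = sim_config(), master_seed = 1,
                               max_iter = 25) {
  if (target_poverty_pct <= 0 || target_poverty_pct >= 100)
    stop("target poverty must be in (0, 100) percent")
  runs <- enumerate_runs(master_seed)
  parent <- runs[runs$run_id == .parent_run_id(runs, "positive"), ]
  poverty_at <- function(scale) {
    s <- sim
    s$hh$income_scale <- scale
    res <- simulate_run(parent, region, archetypes, climatology,
                        master_seed, years, s)
    res$indicators$poverty_rate_pct[res$indicators$year == 2015]
  }
  lo <- bounds[1]; hi <- bounds[2]
  p_lo <- poverty_at(lo); p_hi <- poverty_at(hi)
  # poverty decreases in the income scale
  if (p_lo < target_poverty_pct - tolerance)
    stop("target unattainable: poverty at lower scale bound (", lo,
         ") is already ", round(p_lo, 1), "% < target")
  if (p_hi > target_poverty_pct + tolerance)
    stop("target unattainable: poverty at upper scale bound (", hi,
         ") is still ", round(p_hi, 1), "% > target")
  trace <- data.frame(scale = c(lo, hi), poverty = c(p_lo, p_hi))
  best <- if (abs(p_lo - target_poverty_pct) < abs(p_hi - target_poverty_pct))
    c(lo, p_lo) else c(hi, p_hi)
  for (it in seq_len(max_iter)) {
    if (abs(best[2] - target_poverty_pct) <= tolerance) break
    mid <- (lo + hi) / 2
    p_mid <- poverty_at(mid)
    trace <- rbind(trace, data.frame(scale = mid, poverty = p_mid))
    if (abs(p_mid - target_poverty_pct) < abs(best[2] - target_poverty_pct))
      best <- c(mid, p_mid)
    if (p_mid > target_poverty_pct) lo <- mid else hi <- mid
  }
  if (abs(best[2] - target_poverty_pct) > tolerance)
    stop("calibration did not reach ", target_poverty_pct, " +/- ",
         tolerance, "%; best: scale ", round(best[1], 3), " -> ",
         round(best[2], 1), "% (see trace)")
  list(income_scale = best[1], achieved_poverty_pct = best[2],
       iterations = nrow(trace) - 2, report = trace)
}

#' Apply an absolute asset-loss shock to household states
#'
#' Each household loses `min(assets, amount)`: an identical absolute
#' shock removes a larger fraction of total wealth from poorer
#' households.
#'
#' @param assets,savings current asset and savings vectors
#' @param amount absolute loss per household
#' @return data.frame with new `assets`, the `loss`, and
#'   `wealth_loss_frac` (loss over savings + assets)
#' @export
apply_asset_shock <- function(assets, savings, amount) {
  loss <- pmin(assets, amount)
  data.frame(assets = assets - loss, loss = loss,
             wealth_loss_frac = loss / pmax(assets + savings, 1e-12))
}
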