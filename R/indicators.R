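# Headline livelihood indicators and their temporal aggregations.

#' Population-weighted poverty rate (percent)
#'
#' @param poor logical (or 0/1) poverty flags
#' @param weights population weights (>= 0, not all zero)
#' @return percentage of the population in poor households
#' @export
poverty_rate <- function(poor, weights = rep(1, length(poor))) {
  stopifnot(length(poor) == length(weights), all(weights >= 0))
  tot <- sum(weights)
  if (tot == 0) stop("total population weight is zero")
  100 * sum(weights * as.numeric(poor)) / tot
}

#' Weighted Gini index
#'
#' Mean-absolute-difference form:
#' `G = sum_ij w_i w_j |x_i - x_j| / (2 (sum w)^2 xbar)` with `xbar` the
#' weighted mean.
#'
#' @param values non-negative incomes, at least one positive
#' @param weights population weights
#' @return Gini index in \[0, 1\]
#' @export
gini <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights),
            all(values >= 0), all(weights >= 0))
  if (all(values == 0)) stop("Gini undefined: all incomes are zero")
  w <- weights / sum(weights)
  xbar <- sum(w * values)
  sum(outer(w, w) * abs(outer(values, values, "-"))) / (2 * xbar)
}

#' GDP per capita
#' @param total_income total income over the population (currency)
#' @param population total population (> 0)
#' @return currency per person
#' @export
gdp_per_capita <- function(total_income, population) {
  if (any(population <= 0)) stop("population must be > 0")
  total_income / population
}

#' Mean of a series over a decade
#' @param values annual values
#' @param years matching years
#' @param decade integer length-2: first and last year, inclusive
#' @return arithmetic mean; errors if the decade is not fully covered
#' @export
decadal_mean <- function(values, years, decade = c(2041, 2050)) {
  want <- seq(decade[1], decade[2])
  if (!all(want %in% years)) stop("series does not cover ", decade[1],
                                  "-", decade[2])
  mean(values[match(want, years)])
}

#' Change of a value against the 2005-2014 baseline
#' @param value decadal (or annual) value
#' @param baseline baseline value (mean over 2005-2014)
#' @return list with `abs` (value - baseline) and `pct`
#'   (100 x (value - baseline)/|baseline|; NA when the baseline is 0)
#' @export
baseline_change <- function(value, baseline) {
  list(abs = value - baseline,
       pct = if (baseline == 0) NA_real_
             else 100 * (value - baseline) / abs(baseline))
}
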