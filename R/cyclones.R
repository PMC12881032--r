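# Cyclone event-set generator.
#
# Strong (>= 140 km/h) and weak (80-140 km/h) cyclones are drawn from
# independent homogeneous Poisson processes with per-decade rates taken
# from the scenario, optionally scaled by a frequency multiplier for
# sensitivity runs. Landfall positions are uniform along the coastline
# (parameterised on [0, 1]); event timing within the year follows the
# Bay-of-Bengal bimodal cyclone season (pre- and post-monsoon).

# day-of-year sampling weights: peaks in April-May and October-November
.cyclone_doy_weights <- function() {
  doy <- 1:365
  w <- exp(-((doy - 135) / 25)^2) + exp(-((doy - 305) / 25)^2)
  w / sum(w)
}

#' Generate a cyclone event set
#'
#' @param rate_strong strong-cyclone rate, events per decade
#' @param rate_weak weak-cyclone rate, events per decade
#' @param years integer years to simulate
#' @param seed integer seed
#' @param freq_multiplier non-negative frequency multiplier applied to both
#'   intensities (0.5 / 1 / 1.5 in the sensitivity design)
#' @return data.frame with columns `year`, `doy`, `intensity_class`
#'   ("strong"/"weak"), `wind_speed_kmh`, `landfall_position`
#' @export
generate_cyclones <- function(rate_strong, rate_weak, years, seed,
                              freq_multiplier = 1) {
  if (rate_strong < 0 || rate_weak < 0) stop("cyclone rates must be >= 0")
  if (freq_multiplier < 0) stop("cyclone frequency multiplier must be >= 0")
  set.seed(seed)
  ny <- length(years)
  n_s <- stats::rpois(ny, rate_strong / 10 * freq_multiplier)
  n_w <- stats::rpois(ny, rate_weak / 10 * freq_multiplier)
  n <- sum(n_s) + sum(n_w)
  if (n == 0) {
    return(data.frame(year = integer(), doy = integer(),
                      intensity_class = character(),
                      wind_speed_kmh = numeric(),
                      landfall_position = numeric()))
  }
  year <- c(rep(years, n_s), rep(years, n_w))
  cls <- c(rep("strong", sum(n_s)), rep("weak", sum(n_w)))
  wind <- c(stats::runif(sum(n_s), 140, 250), stats::runif(sum(n_w), 80, 140))
  doy <- sample.int(365L, n, replace = TRUE, prob = .cyclone_doy_weights())
  ev <- data.frame(year = year, doy = doy, intensity_class = cls,
                   wind_speed_kmh = wind,
                   landfall_position = stats::runif(n))
  ev <- ev[order(ev$year, ev$doy), ]
  rownames(ev) <- NULL
  ev
}
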