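# Daily climate series generator.
#
# Anomalies follow a linear ramp in time between the midpoints of the base
# period (2000-2015, midpoint 2007) and the mid-century window (2040-2055,
# midpoint 2047), normalised so that the window-mean difference between the
# two periods equals the configured scenario deltas exactly. Temperature
# anomalies are additive, precipitation anomalies multiplicative. Seasonal
# (monsoon/dry) deltas are reconciled to the annual target by a common
# scale factor: the annual target takes precedence and is exact by
# construction; the seasonal split is approximate.

# Ramp factor f(y): 0 up to 2007, then (y - 2007)/40, not capped above,
# so g(y) = f(y)/c has mean(mid-century) - mean(base) = 1 exactly.
.anomaly_g <- function(years) {
  f <- pmax(0, (years - 2007) / 40)
  fb <- mean(pmax(0, (2000:2015 - 2007) / 40))
  fm <- mean(pmax(0, (2040:2055 - 2007) / 40))
  f / (fm - fb)
}

#' Generate a daily climate series for a scenario world
#'
#' Expands a one-year daily climatology into a transient daily series of
#' temperature, precipitation and a dimensionless river-discharge index,
#' with scenario anomalies ramped in over time. With `noise = FALSE`
#' (the default) the series is fully deterministic and the configured
#' annual temperature and precipitation changes between the base period
#' (2000-2015) and mid-century (2040-2055) are recovered exactly.
#'
#' @param config a `world_config`
#' @param base_stats daily climatology: data.frame with columns `doy`
#'   (1..365), `temp_C`, `precip_mm` and optionally `discharge` (see
#'   [make_climatology()])
#' @param seed integer seed, required when `noise = TRUE`
#' @param years integer years covered (default 1985:2055)
#' @param noise logical; add gamma-distributed daily rainfall noise that
#'   preserves expected totals
#' @return data.frame with columns `year`, `doy`, `month`, `season`,
#'   `temp_C`, `precip_mm`, `discharge_index`
#' @export
generate_climate <- function(config, base_stats, seed = NULL,
                             years = 1985:2055, noise = FALSE) {
  validate_world(config)
  stopifnot(all(c("doy", "temp_C", "precip_mm") %in% names(base_stats)),
            nrow(base_stats) == 365)
  if (noise && is.null(seed))
    stop("a seed is required when stochastic weather noise is enabled")
  base_stats <- base_stats[order(base_stats$doy), ]
  if (is.null(base_stats$discharge))
    base_stats$discharge <- base_stats$precip_mm / mean(base_stats$precip_mm)

  doy <- base_stats$doy
  season <- season_of_doy(doy)
  monsoon <- season == "monsoon"

  # temperature: scale seasonal additive deltas to hit the annual target
  dT <- config$temp_rise_C
  dT_day <- ifelse(monsoon, dT[["monsoon"]], dT[["dry"]])
  mean_dT <- mean(dT_day)
  lam_T <- if (mean_dT != 0) dT[["annual"]] / mean_dT else 0
  dT_day <- dT_day * lam_T

  # precipitation: multiplicative seasonal deltas, common scale factor
  # lambda solving for the exact annual total change between windows
  dP <- config$precip_change_frac
  dP_day <- ifelse(monsoon, dP[["monsoon"]], dP[["dry"]])
  clim_p <- base_stats$precip_mm
  D <- sum(clim_p * dP_day) / sum(clim_p) # rain-weighted mean seasonal delta
  g <- .anomaly_g(years)
  gb <- mean(.anomaly_g(2000:2015))
  gm <- mean(.anomaly_g(2040:2055))
  da <- dP[["annual"]]
  lam_P <- if (D != 0) da / (D * (gm - (1 + da) * gb)) else 0

  n <- length(years)
  out <- data.frame(
    year = rep(years, each = 365L),
    doy = rep(doy, n),
    month = rep(month_of_doy(doy), n),
    season = rep(season, n),
    temp_C = rep(base_stats$temp_C, n) + rep(dT_day, n) * rep(g, each = 365L),
    precip_mm = rep(clim_p, n) *
      pmax(0, 1 + lam_P * rep(dP_day, n) * rep(g, each = 365L)),
    discharge_index = rep(base_stats$discharge, n) *
      pmax(0, 1 + lam_P * D * rep(g, each = 365L))
  )

  if (noise) {
    set.seed(seed)
    wet <- out$precip_mm > 0
    shape <- 0.8 # daily rainfall noise; mean-preserving
    out$precip_mm[wet] <- stats::rgamma(sum(wet), shape = shape,
                                        scale = out$precip_mm[wet] / shape)
  }
  out
}

#' Annual summary of a climate series
#' @param climate output of [generate_climate()]
#' @return data.frame with per-year mean temperature, total precipitation
#'   and mean discharge index
#' @export
annual_climate <- function(climate) {
  agg <- function(v, f) tapply(v, climate$year, f)
  yrs <- sort(unique(climate$year))
  data.frame(year = yrs,
             temp_C = as.numeric(agg(climate$temp_C, mean)),
             precip_mm = as.numeric(agg(climate$precip_mm, sum)),
             discharge_index = as.numeric(agg(climate$discharge_index, mean)))
}
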