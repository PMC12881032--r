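# Crop production: FAO-style crop-coefficient water demand with yield
# limitation factors for water deficit (FAO-33 linear yield response),
# soil salinity (threshold-slope response), temperature and flood
# depth-duration damage. Stress factors combine multiplicatively.

#' Default crop parameter table
#'
#' Two rice seasons are represented: monsoon ("aman") and dry-season
#' irrigated ("boro"). Stage lengths follow the usual four-stage crop
#' coefficient scheme (initial, development, mid, late). The rice salt
#' threshold is overridden per year by the scenario tolerance ramp.
#'
#' @return data.frame of crop parameters
#' @export
default_crops <- function() {
  data.frame(
    name = c("aman", "boro"),
    sow_doy = c(196L, 5L),          # mid July; early January
    stage_initial = c(25L, 25L),
    stage_development = c(30L, 30L),
    stage_mid = c(45L, 45L),
    stage_late = c(30L, 30L),
    kc_initial = c(1.05, 1.05),
    kc_development = c(1.1, 1.15),
    kc_mid = c(1.2, 1.3),
    kc_late = c(0.9, 0.95),
    ky = c(1.1, 1.1),
    salt_threshold_dS_m = c(6, 6),
    salt_slope_per_dS_m = c(0.12, 0.12),
    temp_min_C = c(10, 10),
    temp_opt_lo_C = c(18, 18),
    temp_opt_hi_C = c(33, 33),
    temp_max_C = c(42, 42),
    flood_kill_depth_m = c(0.5, 0.5),
    flood_kill_days = c(5L, 5L),
    potential_yield_t_ha = c(4, 5),
    stringsAsFactors = FALSE
  )
}

#' Reference evapotranspiration (Blaney-Criddle, mm/day)
#'
#' Temperature-only formulation: `ET0 = p (0.46 T + 8.13)` where `p` is
#' the mean daily percentage of annual daytime hours, computed from solar
#' geometry at the region's latitude.
#'
#' @param tmean_C daily mean temperature (vectorised)
#' @param doy day of year matching `tmean_C`
#' @param latitude_deg site latitude (default 22.5, southern Bangladesh)
#' @return ET0 in mm/day (never negative)
#' @export
reference_et <- function(tmean_C, doy, latitude_deg = 22.5) {
  stopifnot(all(tmean_C > -10 & tmean_C < 50))
  p <- daylight_percent(doy, latitude_deg)
  pmax(0, p * (0.46 * tmean_C + 8.13))
}

#' Mean daily percentage of annual daytime hours
#' @inheritParams reference_et
#' @return percentage `p` used by the Blaney-Criddle formula
#' @export
daylight_percent <- function(doy, latitude_deg = 22.5) {
  phi <- latitude_deg * pi / 180
  N_of <- function(d) {
    delta <- 0.409 * sin(2 * pi * d / 365 - 1.39)
    omega <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
    24 * omega / pi
  }
  100 * N_of(doy) / sum(N_of(1:365))
}

#' FAO-33 water stress factor
#' @param eta actual evapotranspiration over the season (mm)
#' @param etm maximum (unstressed) evapotranspiration (mm), > 0
#' @param ky yield response factor
#' @return factor in \[0, 1\]: `1 - ky (1 - eta/etm)`, clipped
#' @export
water_stress_factor <- function(eta, etm, ky) {
  if (any(etm <= 0)) stop("etm must be > 0")
  stopifnot(all(eta >= 0), all(eta <= etm + 1e-9))
  pmin(1, pmax(0, 1 - ky * (1 - eta / etm)))
}

#' Threshold-slope salinity stress factor
#' @param ec seasonal soil salinity (dS/m)
#' @param threshold crop salt tolerance threshold (dS/m)
#' @param slope fractional yield loss per dS/m above the threshold
#' @return factor in \[0, 1\]
#' @export
salt_stress_factor <- function(ec, threshold, slope) {
  stopifnot(all(ec >= 0), all(threshold >= 0), all(slope >= 0))
  ifelse(ec <= threshold, 1, pmax(0, 1 - slope * (ec - threshold)))
}

#' Temperature stress factor over a growing season
#'
#' Daily factor is 1 inside the optimal band, falls linearly to 0 at the
#' kill limits, and is 0 beyond them; the seasonal factor is the mean of
#' the daily factors.
#'
#' @param temps daily mean temperatures over the season
#' @param limits numeric length-4: (kill min, optimal low, optimal high,
#'   kill max)
#' @return factor in \[0, 1\]
#' @export
temp_stress_factor <- function(temps, limits) {
  stopifnot(length(limits) == 4, !is.unsorted(limits))
  tmin <- limits[1]; olo <- limits[2]; ohi <- limits[3]; tmax <- limits[4]
  f <- ifelse(temps >= olo & temps <= ohi, 1,
       ifelse(temps <= tmin | temps >= tmax, 0,
       ifelse(temps < olo, (temps - tmin) / (olo - tmin),
              (tmax - temps) / (tmax - ohi))))
  mean(f)
}

#' Flood damage factor over a growing season
#'
#' Damage scales with the longest consecutive spell of flood depth at or
#' above the kill depth: 1 with no exceedance, 0 once the spell reaches
#' the kill duration, linear in between.
#'
#' @param depths daily flood depths (m) over the season
#' @param kill_depth_m depth threshold (m)
#' @param kill_days duration threshold (days)
#' @return factor in \[0, 1\]
#' @export
flood_damage_factor <- function(depths, kill_depth_m, kill_days) {
  exceed <- depths >= kill_depth_m
  if (!any(exceed)) return(1)
  r <- rle(exceed)
  longest <- max(r$lengths[r$values])
  max(0, 1 - longest / kill_days)
}

#' Seasonal yield under combined stresses
#' @param crop one row of [default_crops()] (list or data.frame row)
#' @param factors numeric vector of stress factors in \[0, 1\] (water,
#'   salt, temperature, flood)
#' @param unit_multiplier crop-improvement unit production multiplier
#' @return yield in t/ha
#' @export
season_yield <- function(crop, factors, unit_multiplier = 1) {
  stopifnot(all(factors >= 0), all(factors <= 1))
  crop$potential_yield_t_ha * unit_multiplier * prod(factors)
}

#' Total regional rice production
#' @param yields_t_ha vector of per-union-season yields (t/ha)
#' @param cropped_area_km2 matching cropped areas (km2)
#' @return total production in tonnes (1 km2 = 100 ha)
#' @export
total_rice_production <- function(yields_t_ha, cropped_area_km2) {
  stopifnot(length(yields_t_ha) == length(cropped_area_km2))
  sum(yields_t_ha * cropped_area_km2 * 100)
}

#' Crop coefficient for each day of a season
#' @param crop one row of [default_crops()]
#' @return data.frame with `doy` (wrapped on the 365-day calendar) and
#'   `kc` for each day of the growing season, plus `day_index`
#' @keywords internal
crop_calendar <- function(crop) {
  lens <- c(crop$stage_initial, crop$stage_development, crop$stage_mid,
            crop$stage_late)
  kcs <- c(crop$kc_initial, crop$kc_development, crop$kc_mid, crop$kc_late)
  kc <- rep(kcs, lens)
  ndays <- sum(lens)
  doy <- ((crop$sow_doy - 1 + seq_len(ndays) - 1) %% 365) + 1
  data.frame(day_index = seq_len(ndays), doy = doy, kc = kc)
}
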