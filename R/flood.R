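# Reduced-form annual flood model over union cells.
#
# The annual maximum coastal water level is tide amplitude + relative sea
# level + the largest cyclone storm surge reaching each cell (surge decays
# along the coast away from the landfall point and inland with distance
# from the coast). A poldered cell floods when the water level exceeds
# elevation + embankment height; an unprotected cell when it exceeds
# elevation; flood depth is the positive excess. A fluvial/pluvial term
# adds partial inundation proportional to discharge x precipitation
# excess. Flood-water salinity decays with distance from the coast.

#' Default flood-model parameters
#'
#' Free parameters of the reduced-form flood rule: tide amplitude, surge
#' heights per cyclone class, the alongshore surge decay half-width and
#' inland decay scale (both as fractions of the region extent), the
#' coastal flood-water salinity and its inland decay scale, the fresh
#' (fluvial) flood salinity, and the fluvial inundation coefficients.
#'
#' @param ... overrides of the defaults
#' @return named list of parameters
#' @export
flood_params <- function(...) {
  p <- list(
    tide_amplitude_m = 1.0,
    surge_strong_m = 3.0,
    surge_weak_m = 1.2,
    surge_halfwidth = 0.25,     # alongshore gaussian half-width, coast fraction
    surge_inland_decay = 0.35,  # e-folding in coast_distance units
    coast_ec_dS_m = 25,         # flood-water salinity at the coast
    ec_decay_distance = 0.4,    # e-folding of flood-water EC inland
    fresh_flood_ec = 0.3,       # fluvial flood-water salinity
    fluvial_coeff = 0.15,       # fraction flooded per (discharge x m excess)
    precip_threshold_mm = 1200, # annual precip above which runoff floods
    fluvial_depth_m = 0.3       # nominal fluvial inundation depth
  )
  over <- list(...)
  p[names(over)] <- over
  p
}

#' Simulate the annual maximum flood state over a region
#'
#' @param cells region data.frame (see [make_region()]); `shore_position`
#'   is optional and defaults to an even spread on the coastline
#' @param sea_level_cm relative sea level for the year (cm above the
#'   year-2000 datum)
#' @param discharge_index dimensionless annual river discharge index
#' @param annual_precip_mm total annual precipitation (mm)
#' @param cyclones cyclone events of the year (possibly empty), as from
#'   [generate_cyclones()]
#' @param params list from [flood_params()]
#' @return object of class `flood_result`: list with `cells` (per-union
#'   `inundated_fraction`, `mean_depth_m`, `floodwater_ec_dS_m`,
#'   `surge_m`) and the aggregate `inundated_area_km2`
#' @export
simulate_flood <- function(cells, sea_level_cm, discharge_index,
                           annual_precip_mm, cyclones = NULL,
                           params = flood_params()) {
  stopifnot(all(c("area_km2", "elevation_m", "poldered",
                  "embankment_height_m", "coast_distance") %in% names(cells)))
  n <- nrow(cells)
  shore <- cells$shore_position
  if (is.null(shore)) shore <- seq(0, 1, length.out = n)

  # largest surge reaching each cell over the year's events
  surge <- rep(0, n)
  if (!is.null(cyclones) && nrow(cyclones) > 0) {
    for (i in seq_len(nrow(cyclones))) {
      h0 <- if (cyclones$intensity_class[i] == "strong")
        params$surge_strong_m else params$surge_weak_m
      s <- h0 * exp(-((shore - cyclones$landfall_position[i]) /
                        params$surge_halfwidth)^2) *
        exp(-cells$coast_distance / params$surge_inland_decay)
      surge <- pmax(surge, s)
    }
  }

  water_level <- params$tide_amplitude_m + sea_level_cm / 100 + surge
  emb <- ifelse(cells$poldered, cells$embankment_height_m, 0)
  coastal_depth <- pmax(0, water_level - cells$elevation_m - emb)
  coastal_flooded <- coastal_depth > 0

  precip_excess <- max(0, annual_precip_mm - params$precip_threshold_mm)
  fluvial_frac <- min(1, params$fluvial_coeff * discharge_index *
                        precip_excess / 1000)
  frac <- pmax(as.numeric(coastal_flooded), fluvial_frac)
  depth <- ifelse(coastal_flooded, coastal_depth,
                  fluvial_frac * params$fluvial_depth_m)

  ec <- ifelse(coastal_flooded,
               params$coast_ec_dS_m *
                 exp(-cells$coast_distance / params$ec_decay_distance),
               params$fresh_flood_ec)
  ec[frac == 0] <- 0

  res <- data.frame(union_id = cells$union_id,
                    inundated_fraction = frac,
                    mean_depth_m = depth,
                    floodwater_ec_dS_m = ec,
                    surge_m = surge)
  structure(list(cells = res,
                 inundated_area_km2 = sum(frac * cells$area_km2)),
            class = "flood_result")
}

#' Forcing summaries used to train the flood emulator
#'
#' Expands raw annual forcings into the summary statistics the emulator
#' is trained on: sea level and its square (embankment overtopping makes
#' the flood response convex in sea level), the discharge index, annual
#' precipitation and the fluvial forcing product
#' `discharge x max(0, precip - threshold)`.
#'
#' @param sea_level_cm,discharge_index,annual_precip_mm raw forcings
#'   (vectorised)
#' @param params [flood_params()] (for the precipitation threshold)
#' @return numeric matrix of forcing summaries, one row per case
#' @export
flood_forcing_summaries <- function(sea_level_cm, discharge_index,
                                    annual_precip_mm,
                                    params = flood_params()) {
  cbind(slr = sea_level_cm,
        slr_sq = sea_level_cm^2,
        discharge = discharge_index,
        precip = annual_precip_mm,
        fluvial = discharge_index *
          pmax(0, annual_precip_mm - params$precip_threshold_mm) / 1000)
}

#' @export
print.flood_result <- function(x, ...) {
  cat("<flood_result>", nrow(x$cells), "unions;",
      round(x$inundated_area_km2, 1), "km2 inundated\n")
  invisible(x)
}
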