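# Daily root-zone water and salt balance (single bucket per union).
#
# Water: W' = W + P + I + F_inf + C - ET - percolation - drainage, with
# percolation = drainage_coeff x max(0, W - field-capacity store) and
# overflow above saturation routed to surface drainage. Salt (stored as
# mm x dS/m so that EC = salt / water) enters with irrigation, infiltrated
# flood water and capillary rise, and leaves with percolation (scaled by
# the leaching efficiency) and surface drainage at the current
# concentration. Every flux is returned so that mass closure can be
# audited exactly.

#' Soil parameter set
#' @param ... overrides of the defaults
#' @return named list with porosity, field capacity, maximum root zone
#'   depth (m), drainage coefficient (1/day), capillary rise rate
#'   (mm/day), capillary-water salinity (dS/m), leaching efficiency and
#'   the fraction of standing flood depth infiltrating per day
#' @export
soil_params <- function(...) {
  p <- list(porosity = 0.45, field_capacity = 0.30, wilting_point = 0.10,
            root_zone_max_m = 0.6,
            drainage_coeff_per_day = 0.15, capillary_rate_mm_day = 0.3,
            capillary_salinity_dS_m = 10, leaching_efficiency = 0.9,
            flood_infiltration_frac = 0.1)
  over <- list(...)
  p[names(over)] <- over
  stopifnot(p$field_capacity > 0, p$field_capacity <= p$porosity,
            p$porosity <= 1, p$wilting_point >= 0,
            p$wilting_point < p$field_capacity,
            p$leaching_efficiency >= 0, p$leaching_efficiency <= 1)
  p
}

#' Initialise soil state
#' @param n number of cells
#' @param params soil parameters
#' @param ec_dS_m initial soil salinity
#' @param root_depth_m initial root-zone depth
#' @return list of vectors `water_mm`, `salt` (mm x dS/m), `root_depth_m`
#' @export
soil_init <- function(n, params = soil_params(), ec_dS_m = 4,
                      root_depth_m = 0.5) {
  w <- rep(params$field_capacity * root_depth_m * 1000, n)
  list(water_mm = w, salt = w * ec_dS_m, root_depth_m = rep(root_depth_m, n))
}

#' Advance the soil water and salt balance by one day
#'
#' All arguments are vectorised over cells. Evapotranspiration demand
#' exceeding the available water is capped and flagged.
#'
#' @param state list as from [soil_init()]
#' @param params soil parameters from [soil_params()]
#' @param precip_mm rainfall depth (assumed fresh, EC 0)
#' @param et_mm evapotranspiration demand
#' @param irrigation_mm,irrigation_ec irrigation depth and salinity
#' @param flood_depth_m,flood_ec standing flood depth (m) and salinity; a
#'   fixed fraction of the standing depth infiltrates per day
#' @param capillary_ec capillary-rise salinity (defaults to the parameter
#'   value; pass a vector for coastal decay)
#' @param root_depth_m target root-zone depth for the day (crop-calendar
#'   driven); soil newly included when the zone deepens enters at field
#'   capacity with capillary salinity
#' @param drainage_open logical; when TRUE, water above saturation leaves
#'   as surface drainage (carrying salt at the current concentration)
#' @param diagnostics when FALSE, skip building the flux table (faster in
#'   long simulation loops); `et_actual` is still returned
#' @return list with the new `state`, `et_actual`, and (when
#'   `diagnostics = TRUE`) a `fluxes` data.frame of all water and salt
#'   flows plus `et_capped`
#' @export
step_soil_day <- function(state, params, precip_mm, et_mm,
                          irrigation_mm = 0, irrigation_ec = 0,
                          flood_depth_m = 0, flood_ec = 0,
                          capillary_ec = NULL, root_depth_m = NULL,
                          drainage_open = TRUE, diagnostics = TRUE) {
  n <- length(state$water_mm)
  rec <- function(x) rep_len(x, n)
  P <- rec(precip_mm); ETd <- rec(et_mm)
  I <- rec(irrigation_mm); Iec <- rec(irrigation_ec)
  Fd <- rec(flood_depth_m); Fec <- rec(flood_ec)
  if (any(P < 0 | ETd < 0 | I < 0 | Fd < 0)) stop("fluxes must be >= 0")
  Cec <- if (is.null(capillary_ec)) rep(params$capillary_salinity_dS_m, n)
         else rec(capillary_ec)

  W <- state$water_mm; S <- state$salt; rd <- state$root_depth_m

  # root-zone adjustment (book-kept as explicit in/outflows)
  root_in_w <- root_in_s <- root_out_w <- root_out_s <- rep(0, n)
  if (!is.null(root_depth_m)) {
    rd_new <- rec(root_depth_m)
    deeper <- rd_new > rd
    if (any(deeper)) {
      add_w <- (rd_new - rd) * 1000 * params$field_capacity
      root_in_w[deeper] <- add_w[deeper]
      root_in_s[deeper] <- add_w[deeper] * Cec[deeper]
    }
    shallower <- rd_new < rd
    if (any(shallower)) {
      frac <- pmin(1, pmax(0, (rd - rd_new) / rd))
      root_out_w[shallower] <- W[shallower] * frac[shallower]
      root_out_s[shallower] <- S[shallower] * frac[shallower]
    }
    W <- W + root_in_w - root_out_w
    S <- S + root_in_s - root_out_s
    rd <- rd_new
  }

  Cap <- rep(params$capillary_rate_mm_day, n)
  Finf <- params$flood_infiltration_frac * Fd * 1000
  W_in <- W + P + I + Finf + Cap
  S_in <- S + I * Iec + Finf * Fec + Cap * Cec

  # evapotranspiration cannot draw water below the wilting point
  wilt_store <- params$wilting_point * rd * 1000
  ET <- pmin(ETd, pmax(0, W_in - wilt_store))
  et_capped <- ET < ETd
  W1 <- W_in - ET

  fc_store <- params$field_capacity * rd * 1000
  sat_store <- params$porosity * rd * 1000
  perc <- params$drainage_coeff_per_day * pmax(0, W1 - fc_store)
  over <- pmax(0, W1 - perc - sat_store)
  open <- rep_len(drainage_open, n)
  drain <- over * as.numeric(open)
  # with drainage closed the excess ponds and percolates instead
  perc <- perc + (over - drain)

  conc <- S_in / pmax(W1, 1e-12)
  salt_perc <- params$leaching_efficiency * conc * perc
  salt_drain <- conc * drain

  W2 <- W1 - perc - drain
  S2 <- pmax(0, S_in - salt_perc - salt_drain)

  state <- list(water_mm = W2, salt = S2, root_depth_m = rd)
  if (!diagnostics)
    return(list(state = state, et_actual = ET))
  fluxes <- data.frame(
    precip = P, irrigation = I, flood_infiltration = Finf, capillary = Cap,
    et = ET, percolation = perc, drainage = drain,
    root_in_w = root_in_w, root_out_w = root_out_w,
    salt_in = I * Iec + Finf * Fec + Cap * Cec,
    salt_perc = salt_perc, salt_drain = salt_drain,
    root_in_s = root_in_s, root_out_s = root_out_s,
    et_capped = et_capped)
  list(state = state, et_actual = ET, fluxes = fluxes)
}

#' Soil salinity of a state (dS/m)
#' @param state soil state
#' @return EC vector; zero-water cells report 0
#' @export
soil_ec <- function(state) {
  ifelse(state$water_mm > 0, state$salt / state$water_mm, 0)
}

#' Annual salinity statistics
#' @param daily_ec numeric vector of daily EC values over one year
#' @return named vector with `max` and `mean`
#' @export
annual_salinity_stats <- function(daily_ec) {
  if (length(daily_ec) == 0) stop("empty salinity series")
  c(max = max(daily_ec), mean = mean(daily_ec))
}
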