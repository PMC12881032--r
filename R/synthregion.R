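# Synthetic study region generator.
#
# Stands in for the real delta geography: a grid of "union" cells
# (~26 km^2, ~21,000 people each, a poldered/unprotected split, elevations
# falling toward the coast), a baseline daily climatology with
# monsoon-concentrated rainfall, and 36 archetypal households built from
# six occupation types x three landholding classes x two income-mix
# variants, matching the region's published marginal shares (~56%
# functionally landless, ~85% engaged in agriculture, ~70% with mixed
# income sources).

#' Generate a synthetic union-cell region
#'
#' @param seed integer seed; generation is a pure function of
#'   (seed, arguments)
#' @param n_unions number of cells (>= 4; default 64, full scale 653)
#' @param poldered_fraction fraction of cells enclosed by embankments
#' @param embankment_height_m design embankment height for poldered cells
#' @return data.frame with one row per union: `union_id`, `area_km2`,
#'   `elevation_m`, `poldered`, `embankment_height_m`, `coast_distance`,
#'   `shore_position`, `population`
#' @export
make_region <- function(seed = 1, n_unions = 64, poldered_fraction = 0.6,
                        embankment_height_m = 1.5) {
  if (n_unions < 4) stop("n_unions must be >= 4")
  set.seed(seed)
  ncol_grid <- max(2L, floor(sqrt(n_unions)))
  idx <- seq_len(n_unions) - 1L
  col <- idx %% ncol_grid
  row <- idx %/% ncol_grid
  nrow_grid <- max(row) + 1L
  coast_distance <- if (nrow_grid > 1) row / (nrow_grid - 1L) else rep(0, n_unions)
  shore_position <- if (ncol_grid > 1) col / (ncol_grid - 1L) else rep(0.5, n_unions)
  elevation <- pmin(3, pmax(0.05,
    3 * coast_distance + stats::rnorm(n_unions, 0, 0.25)))
  area <- stats::runif(n_unions, 26 * 0.7, 26 * 1.3)
  population <- round(stats::rlnorm(n_unions, log(21000) - 0.3^2 / 2, 0.3))
  poldered <- rep(FALSE, n_unions)
  if (poldered_fraction > 0) {
    n_pold <- round(poldered_fraction * n_unions)
    # polders concentrated in the low-lying coastal half
    ord <- order(coast_distance, stats::runif(n_unions))
    poldered[ord[seq_len(n_pold)]] <- TRUE
  }
  data.frame(
    union_id = sprintf("u%03d", idx),
    area_km2 = area,
    elevation_m = elevation,
    poldered = poldered,
    embankment_height_m = ifelse(poldered, embankment_height_m, 0),
    coast_distance = coast_distance,
    shore_position = shore_position,
    population = population
  )
}

#' Baseline daily climatology
#'
#' Sinusoidal temperature (annual mean ~26 C, amplitude 5 C, peak in
#' May) and monsoon-concentrated rainfall whose June-October share of the
#' annual total is set by `monsoon_share` using a smooth von-Mises-shaped
#' seasonal weight. The discharge index follows a smoothed rainfall
#' seasonality normalised to mean 1.
#'
#' @param annual_precip_mm total annual precipitation (mm)
#' @param monsoon_share fraction of annual rain falling June-October
#' @param temp_mean_C,temp_amplitude_C annual temperature cycle parameters
#' @return data.frame with columns `doy`, `temp_C`, `precip_mm`,
#'   `discharge`
#' @export
make_climatology <- function(annual_precip_mm = 2000, monsoon_share = 0.8,
                             temp_mean_C = 26, temp_amplitude_C = 5) {
  doy <- 1:365
  temp <- temp_mean_C + temp_amplitude_C * sin(2 * pi * (doy - 40) / 365)
  monsoon <- season_of_doy(doy) == "monsoon"
  # von-Mises-shaped weight centred on 1 August (doy 213); concentration
  # solved so the monsoon share of rain matches the target
  share_at <- function(k) {
    w <- exp(k * cos(2 * pi * (doy - 213) / 365))
    sum(w[monsoon]) / sum(w)
  }
  k <- stats::uniroot(function(k) share_at(k) - monsoon_share,
                      c(0.01, 20))$root
  w <- exp(k * cos(2 * pi * (doy - 213) / 365))
  precip <- annual_precip_mm * w / sum(w)
  # discharge lags rainfall by ~1 month (upstream routing), mean 1
  lag <- 30L
  w_lag <- w[((doy - 1 - lag) %% 365) + 1]
  data.frame(doy = doy, temp_C = temp, precip_mm = precip,
             discharge = w_lag / mean(w_lag))
}

OCCUPATIONS <- c("farming", "farm_labour", "fishing", "forest",
                 "manufacturing", "business")

# population weight of each occupation-dominance type and, within type,
# the landless/small/large landholding split; chosen so the weighted
# marginals reproduce the region's published shares
.archetype_weights <- function() {
  type_w <- c(farming = 0.25, farm_labour = 0.20, fishing = 0.08,
              forest = 0.04, manufacturing = 0.18, business = 0.25)
  land_split <- rbind(
    farming = c(0.30, 0.45, 0.25),
    farm_labour = c(0.80, 0.15, 0.05),
    fishing = c(0.70, 0.20, 0.10),
    forest = c(0.70, 0.20, 0.10),
    manufacturing = c(0.60, 0.30, 0.10),
    business = c(0.55, 0.25, 0.20))
  colnames(land_split) <- c("landless", "small", "large")
  list(type_w = type_w, land_split = land_split)
}

#' Generate the 36 household archetypes
#'
#' Archetypes are 6 occupation-dominance types x 3 landholding classes
#' (landless / small / large) x 2 income-mix variants (specialised /
#' mixed). Population weights are constructed so that approximately 56%
#' of the population is functionally landless, at least 80% has nonzero
#' agricultural engagement and about 70% has mixed income sources.
#'
#' @param seed integer seed (minor jitter on monetary parameters)
#' @param mixed_fraction fraction of each type's weight on the mixed
#'   variant
#' @return data.frame with 36 rows: occupation shares (six columns),
#'   `members`, `land_ha`, `assets_value`, `initial_savings`,
#'   `monthly_food_need`, `monthly_nonfood_need`,
#'   `fixed_livelihood_costs`, `group`, `landholding_class`, `weight`
#' @export
make_archetypes <- function(seed = 1, mixed_fraction = 0.7) {
  set.seed(seed)
  w <- .archetype_weights()
  rows <- list()
  for (type in OCCUPATIONS) {
    for (land in c("landless", "small", "large")) {
      for (variant in c("specialised", "mixed")) {
        shares <- stats::setNames(rep(0, 6), OCCUPATIONS)
        dom <- if (variant == "specialised") 0.85 else 0.45
        shares[type] <- dom
        # the remainder is spread over complementary sources
        others <- setdiff(OCCUPATIONS, type)
        spread <- c(farming = 0.20, farm_labour = 0.30, fishing = 0.10,
                    forest = 0.05, manufacturing = 0.15, business = 0.20)
        shares[others] <- (1 - dom) * spread[others] / sum(spread[others])
        if (variant == "specialised") {
          # specialised households draw only on their dominant source,
          # except service households who keep a sliver of farm labour
          shares[] <- 0
          shares[type] <- 1
          if (type %in% c("manufacturing", "business") && land != "landless") {
            shares[type] <- 0.9
            shares["farming"] <- 0.1
          }
        }
        if (land == "landless" && shares["farming"] > 0) {
          # landless households cannot earn own-farm income: sharecropping
          # and field work appear as farm labour instead
          shares["farm_labour"] <- shares["farm_labour"] + shares["farming"]
          shares["farming"] <- 0
        }
        land_ha <- switch(land, landless = 0, small = 0.4, large = 2.0)
        members <- if (variant == "mixed") 5L else 4L
        wealth <- switch(land, landless = 1, small = 1.8, large = 3.5)
        vf <- if (variant == "mixed") mixed_fraction else 1 - mixed_fraction
        weight <- w$type_w[[type]] * w$land_split[type, land] * vf
        rows[[length(rows) + 1L]] <- data.frame(
          archetype_id = paste(type, land, variant, sep = "_"),
          t(shares), members = members, land_ha = land_ha,
          assets_value = 30000 * wealth * stats::runif(1, 0.9, 1.1),
          initial_savings = 4000 * wealth * stats::runif(1, 0.9, 1.1),
          monthly_food_need = 1150 * members,
          monthly_nonfood_need = 700 * members,
          fixed_livelihood_costs = 400 + 600 * land_ha,
          landholding_class = land, variant = variant, weight = weight,
          stringsAsFactors = FALSE)
      }
    }
  }
  arch <- do.call(rbind, rows)
  arch$weight <- arch$weight / sum(arch$weight)
  farm_share <- arch$farming + arch$fishing + arch$forest
  service_share <- arch$manufacturing + arch$business
  arch$group <- ifelse(farm_share + arch$farm_labour >= 0.6, "farm-based",
                ifelse(service_share >= 0.6, "service", "mixed"))
  rownames(arch) <- NULL
  arch
}

#' Household group label used in the poverty attribution
#'
#' Six groups: livelihood group (farm-based / mixed / service) crossed
#' with landless vs landed.
#' @param archetypes output of [make_archetypes()]
#' @return character vector of group labels, one per archetype
#' @export
attribution_group <- function(archetypes) {
  paste(archetypes$group,
        ifelse(archetypes$landholding_class == "landless",
               "landless", "landed"))
}
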