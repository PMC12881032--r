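# Simple 365-day model calendar shared by all modules. Leap days are not
# represented: every simulated year has 365 days and the standard month
# lengths with February fixed at 28 days.

MONTH_DAYS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
MONTH_END  <- cumsum(MONTH_DAYS)
MONTH_START <- c(1L, head(MONTH_END, -1L) + 1L)

#' Month number (1-12) for a day of year on the 365-day model calendar
#' @param doy integer day of year in 1..365
#' @return integer month
#' @keywords internal
month_of_doy <- function(doy) {
  findInterval(doy, MONTH_START)
}

#' Season tag for a day of year
#'
#' The monsoon season is June-October; the dry season is November-May.
#'
#' @param doy integer day of year in 1..365
#' @return character vector, "monsoon" or "dry"
#' @export
season_of_doy <- function(doy) {
  m <- month_of_doy(doy)
  ifelse(m >= 6L & m <= 10L, "monsoon", "dry")
}

# Days per season on the model calendar
MONSOON_DAYS <- sum(MONTH_DAYS[6:10]) # 153
DRY_DAYS <- 365L - MONSOON_DAYS       # 212
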