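#' Daylength from solar declination and latitude
#'
#' Hours from sunrise to sunset for a given latitude and day of year, from the
#' standard solar-geometry approximation: declination
#' \eqn{\delta = -23.44^\circ \cos(2\pi (doy + 10)/365)} and sunset hour angle
#' \eqn{\cos \omega_0 = -\tan(lat)\tan(\delta)}. The cosine is clamped to
#' \eqn{[-1, 1]} so polar day/night degenerate to 24 h / 0 h; the formula is
#' validated for \eqn{|lat| \le 66.5^\circ} and warns outside that band.
#'
#' @param latitude Latitude in decimal degrees (positive north).
#' @param doy Day of year, 1-366. Vectorised.
#' @return Daylength in hours, in `[0, 24]`.
#' @examples
#' compute_daylength(46.815, 172) # summer solstice at a subalpine site
#' @export
compute_daylength <- function(latitude, doy) {
  stopifnot(is.numeric(latitude), length(latitude) == 1, is.numeric(doy))
  if (any(doy < 1 | doy > 366, na.rm = TRUE)) {
    stop("`doy` must be within 1..366", call. = FALSE)
  }
  if (abs(latitude) > 66.5) {
    warning("latitude outside the validated band (|lat| <= 66.5); ",
            "hour-angle cosine clamped", call. = FALSE)
  }
  decl <- -23.44 * pi / 180 * cos(2 * pi * (doy + 10) / 365)
  cos_w0 <- -tan(latitude * pi / 180) * tan(decl)
  cos_w0 <- pmin(pmax(cos_w0, -1), 1)
  pmin(pmax(24 / pi * acos(cos_w0), 0), 24)
}

#' Vapor pressure deficit from air temperature and relative humidity
#'
#' Magnus-form saturation vapor pressure
#' \eqn{e_s(T) = 6.1078 \exp(17.27 T / (T + 237.3))} hPa, so
#' \eqn{VPD = e_s(T)(1 - RH/100)}.
#'
#' @param t_air Air temperature in degrees C. Vectorised.
#' @param rh Relative humidity in percent, within `[0, 100]`.
#' @return VPD in hPa (non-negative).
#' @examples
#' compute_vpd(25, 50)
#' @export
compute_vpd <- function(t_air, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) {
    stop("`rh` must be within [0, 100] percent", call. = FALSE)
  }
  es <- 6.1078 * exp(17.27 * t_air / (t_air + 237.3))
  es * (1 - rh / 100)
}

#' Assign climatological seasons (DJF/MAM/JJA/SON) with season-year
#'
#' December is assigned to the DJF season of the *following* calendar year, the
#' usual climatological convention, so that each winter is contiguous. All
#' other months keep their calendar year as season-year.
#'
#' @param dates A `Date` vector.
#' @return A tibble with columns `date`, `season` (factor DJF/MAM/JJA/SON) and
#'   `season_year`.
#' @examples
#' assign_season(as.Date(c("2010-12-15", "2011-03-01")))
#' @export
assign_season <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  m <- lubridate::month(dates)
  y <- lubridate::year(dates)
  season <- dplyr::case_when(
    m %in% c(12, 1, 2) ~ "DJF",
    m %in% 3:5 ~ "MAM",
    m %in% 6:8 ~ "JJA",
    TRUE ~ "SON"
  )
  tibble(
    date = dates,
    season = factor(season, levels = c("DJF", "MAM", "JJA", "SON")),
    season_year = ifelse(m == 12, y + 1L, y)
  )
}

#' Hours per day with air temperature below 0 degrees C
#'
#' Assumes the within-day temperature course moves linearly between the daily
#' minimum and maximum, so the fraction of the day below freezing is the
#' position of 0 degrees C within `[t_min, t_max]`.
#'
#' @param t_min,t_max Daily minimum / maximum air temperature (degrees C).
#' @return Hours in `[0, 24]`.
#' @export
hours_below_zero <- function(t_min, t_max) {
  frac <- ifelse(
    t_max <= t_min,                 # degenerate constant day
    as.numeric(t_min < 0),
    pmin(pmax((0 - t_min) / (t_max - t_min), 0), 1)
  )
  24 * frac
}
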