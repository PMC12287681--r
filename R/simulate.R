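#' Generate a synthetic daily meteorology table
#'
#' Each variable follows
#' `mean + amplitude * cos(2*pi*(doy - phase)/365) + trend * (year - start_year)`
#' plus stationary AR(1) Gaussian noise (marginal standard deviation `sd`,
#' lag-1 autocorrelation `ar1`, initialised at the stationary distribution).
#' Relative humidity and soil water content are clipped to `[0, 100]` %,
#' radiation and precipitation to non-negative values. Minimum/mean/maximum
#' air temperature are ordered after noise is added so the daily invariant
#' `t_air_min <= t_air_mean <= t_air_max` always holds. Hours below 0 C are
#' derived from the daily extremes by linear within-day interpolation;
#' daylength, VPD and PPFD (scaled from shortwave radiation with the standard
#' ~2.04 umol J^-1 conversion) are filled in from the same table.
#'
#' Feb 29 is generated (so the calendar is complete) but flagged with
#' `leap_day = TRUE`; day-of-year analyses drop it.
#'
#' @param scenario A [flux_scenario()].
#' @return A met-driver tibble: `date`, `year`, `doy`, `leap_day`,
#'   `t_air_mean`, `t_air_min`, `t_air_max`, `hours_below_0`, `rg`, `ppfd`,
#'   `prec`, `rh`, `swc`, `vpd`, `daylength`.
#' @export
generate_met <- function(scenario) {
  stopifnot(inherits(scenario, "flux_scenario"))
  validate_scenario(scenario)
  dates <- seq(
    as.Date(sprintf("%d-01-01", scenario$start_year)),
    as.Date(sprintf("%d-12-31", scenario$start_year + scenario$n_years - 1L)),
    by = "day"
  )
  doy <- lubridate::yday(dates)
  year <- lubridate::year(dates)
  yr_off <- year - scenario$start_year
  n <- length(dates)

  raw <- withr::with_seed(scenario$seed, {
    # fixed variable order keeps the single RNG stream reproducible
    purrr::map(scenario$seasonal, function(p) {
      p$mean + p$amplitude * cos(2 * pi * (doy - p$phase) / 365) +
        p$trend * yr_off + ar1_noise(n, p$sd, p$ar1)
    })
  })

  t_mean <- raw$t_air_mean
  t_min <- pmin(raw$t_air_min, t_mean)
  t_max <- pmax(raw$t_air_max, t_mean)
  rg <- pmax(raw$rg, 0)
  rh <- pmin(pmax(raw$rh, 0), 100)
  swc <- pmin(pmax(raw$swc, 0), 100)
  prec <- pmax(raw$prec, 0)

  tibble(
    date = dates,
    year = year,
    doy = doy,
    leap_day = lubridate::month(dates) == 2 & lubridate::mday(dates) == 29,
    t_air_mean = t_mean,
    t_air_min = t_min,
    t_air_max = t_max,
    hours_below_0 = hours_below_zero(t_min, t_max),
    rg = rg,
    ppfd = 2.04 * rg,
    prec = prec,
    rh = rh,
    swc = swc,
    vpd = compute_vpd(t_mean, rh),
    daylength = compute_daylength(scenario$latitude, pmin(doy, 366))
  )
}

# stationary AR(1) with marginal sd `sigma`
ar1_noise <- function(n, sigma, ar1) {
  if (sigma == 0) return(rep(0, n))
  innov_sd <- sigma * sqrt(1 - ar1^2)
  e <- rnorm(n, 0, innov_sd)
  e[1] <- rnorm(1, 0, sigma)
  as.numeric(stats::filter(e, ar1, method = "recursive", init = 0))
}

# piecewise-linear temperature response: 0 -> 1 on [t_low, t_opt],
# 1 -> 0 on [t_opt, t_high]
temperature_ramp <- function(t, t_low, t_opt, t_high) {
  up <- (t - t_low) / (t_opt - t_low)
  down <- (t_high - t) / (t_high - t_opt)
  pmin(pmax(pmin(up, down), 0), 1)
}

#' Generate synthetic daily NEE from a met table
#'
#' Daily NEE (negative = net uptake) is respiration minus uptake plus noise:
#' \deqn{NEE_d = r_0 q_{10}^{(T_d-10)/10} - lue \cdot Rg_d \cdot ramp(T_d)
#'   \cdot \frac{SWC_d}{SWC_d + swc_{1/2}} + trend \cdot (year_d - year_0)
#'   + \varepsilon_d}
#' with \eqn{T_d} the daily mean air temperature and \eqn{\varepsilon_d}
#' stationary AR(1) Gaussian noise. The per-year ground-truth transition days
#' are recorded from the *noise-free* series with the same extractor settings
#' as [extract_cup()] (10-day trailing average, 14-day persistence) and
#' attached as attribute `"truth"` (tibble `year`, `sos_doy`, `eos_doy`);
#' retrieve it with [nee_truth()].
#'
#' @param scenario The [flux_scenario()] used for `generate_met()`.
#' @param met Met table from [generate_met()]; must cover the scenario span.
#' @return Tibble `date`, `year`, `doy`, `leap_day`, `nee` (g C m^-2 d^-1)
#'   with attribute `truth`.
#' @export
generate_daily_nee <- function(scenario, met) {
  stopifnot(inherits(scenario, "flux_scenario"))
  needed <- c("date", "year", "doy", "t_air_mean", "rg", "swc")
  if (!all(needed %in% names(met))) {
    stop("met table lacks required columns", call. = FALSE)
  }
  expected_years <- scenario$start_year + seq_len(scenario$n_years) - 1L
  if (!setequal(unique(met$year), expected_years)) {
    stop("met table does not cover the scenario span", call. = FALSE)
  }
  p <- scenario$nee
  resp <- p$r0 * p$q10^((met$t_air_mean - 10) / 10)
  uptake <- p$lue * met$rg *
    temperature_ramp(met$t_air_mean, p$t_low, p$t_opt, p$t_high) *
    met$swc / (met$swc + p$swc_half)
  drift <- p$trend * (met$year - scenario$start_year)
  clean <- resp - uptake + drift
  noise <- withr::with_seed(scenario$seed + 1L, ar1_noise(nrow(met), p$sd, p$ar1))

  out <- tibble(
    date = met$date,
    year = met$year,
    doy = met$doy,
    leap_day = met$leap_day %||% FALSE,
    nee = clean + noise
  )
  truth <- tibble(date = met$date, nee = clean) %>%
    extract_cup_all(window = 10, alignment = "trailing", persistence = 14,
                    min_coverage = 300) %>%
    dplyr::select("year", "sos_doy", "eos_doy")
  attr(out, "truth") <- truth
  out
}

#' Ground-truth transition days recorded by the synthetic NEE generator
#'
#' @param daily Output of [generate_daily_nee()].
#' @return Tibble `year`, `sos_doy`, `eos_doy` (noise-free truth).
#' @export
nee_truth <- function(daily) {
  truth <- attr(daily, "truth")
  if (is.null(truth)) stop("no ground truth attached to this series", call. = FALSE)
  truth
}

#' Disaggregate daily NEE to a half-hourly flux series
#'
#' Each daily carbon sum is split into 48 half-hourly fluxes
#' (umol CO2 m^-2 s^-1): a flat respiration baseline of
#' `max(daily, 1)` g C m^-2 d^-1 plus a negative uptake component shaped as a
#' half-sine over the daylight hours, so the flux-unit daily integral equals
#' the daily value by construction (within floating-point error). Optional
#' Gaussian noise is centered per day (mean removed) so the integral is
#' preserved exactly.
#'
#' @param daily Data frame with `date` and `nee` (g C m^-2 d^-1); missing
#'   days give 48 missing half-hours.
#' @param latitude Latitude used for the daylight window (degrees).
#' @param seed Integer seed for the optional noise.
#' @param noise_sd Standard deviation of the per-half-hour noise
#'   (umol CO2 m^-2 s^-1), default 0.
#' @return Tibble `timestamp_start`, `timestamp_end`, `nee`.
#' @export
generate_halfhourly_nee <- function(daily, latitude = 46.815, seed = 1L,
                                    noise_sd = 0) {
  stopifnot(all(c("date", "nee") %in% names(daily)))
  daily <- dplyr::arrange(daily, .data$date)
  doy <- lubridate::yday(daily$date)
  dl <- compute_daylength(latitude, doy)
  hours <- (seq_len(48) - 0.5) * 0.5         # half-hour midpoints

  per_day <- purrr::pmap(
    list(daily$nee, dl),
    function(d, daylen) {
      if (is.na(d)) return(rep(NA_real_, 48))
      resp <- max(d, 1)
      uptake <- d - resp                      # <= 0
      if (daylen > 0) {
        s <- sin(pi * (hours - (12 - daylen / 2)) / daylen)
        s[hours < 12 - daylen / 2 | hours > 12 + daylen / 2] <- 0
        s <- if (sum(s) > 0) s / sum(s) else rep(1 / 48, 48)
      } else {
        s <- rep(1 / 48, 48)
      }
      grams <- resp / 48 + uptake * s
      grams / (1800 * GC_PER_UMOL)
    }
  )
  flux <- unlist(per_day)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, rnorm(length(flux), 0, noise_sd))
    noise <- noise - rep(
      tapply(noise, rep(seq_len(nrow(daily)), each = 48), mean),
      each = 48
    )
    flux <- flux + noise
  }
  start <- rep(as.POSIXct(daily$date, tz = "UTC"), each = 48) +
    rep((seq_len(48) - 1) * 1800, times = nrow(daily))
  tibble(
    timestamp_start = start,
    timestamp_end = start + 1800,
    nee = flux
  )
}
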