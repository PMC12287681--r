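#' Annual and seasonal means, SDs and trends per variable
#'
#' For every met variable and for daily NEE, computes the per-year (and
#' per-season-year) aggregate, then Mann-Kendall + Theil-Sen trends across
#' years. Aggregation rules follow flux-climatology convention: means for
#' state variables (temperatures, VPD, RH, SWC, Rg, PPFD), sums for
#' precipitation and NEE, the annual minimum of daily minima for `t_air_min`,
#' the annual maximum of daily maxima for `t_air_max`, and the annual sum of
#' hours below 0 C. Seasons are climatological (December counts toward the
#' following year's DJF). Variables with fewer than 3 years of coverage are
#' skipped with a warning. Significance stars: `*` for p < 0.05, `**` for
#' p < 0.01.
#'
#' @param met Met-driver table (see [generate_met()] for the column layout).
#' @param daily Daily NEE table with `date` and `nee`.
#' @param alpha Significance level for the `significant` flag.
#' @return Tibble with one row per variable x period (`full_year`, `DJF`,
#'   `MAM`, `JJA`, `SON`): `mean`, `sd`, trend columns and `stars`.
#' @export
annual_seasonal_trend_table <- function(met, daily, alpha = 0.05) {
  rules <- c(
    t_air_mean = "mean", t_air_min = "min", t_air_max = "max",
    hours_below_0 = "sum", vpd = "mean", rh = "mean", swc = "mean",
    rg = "mean", ppfd = "mean", prec = "sum", nee = "sum"
  )
  combined <- dplyr::full_join(
    met, dplyr::select(daily, "date", "nee"), by = "date"
  )
  vars <- intersect(names(rules), names(combined))
  seas <- assign_season(combined$date)
  combined$season <- seas$season
  combined$season_year <- seas$season_year
  combined$cal_year <- lubridate::year(combined$date)

  aggregate_one <- function(v, rule, period) {
    if (period == "full_year") {
      grp <- combined %>% dplyr::group_by(year = .data$cal_year)
    } else {
      grp <- combined %>%
        dplyr::filter(.data$season == period) %>%
        dplyr::group_by(year = .data$season_year)
    }
    agg <- grp %>%
      dplyr::summarise(
        value = switch(rule,
          mean = mean(.data[[v]], na.rm = TRUE),
          sum = sum(.data[[v]], na.rm = TRUE),
          min = suppressWarnings(min(.data[[v]], na.rm = TRUE)),
          max = suppressWarnings(max(.data[[v]], na.rm = TRUE))
        ),
        n_days = sum(!is.na(.data[[v]])),
        .groups = "drop"
      ) %>%
      dplyr::filter(.data$n_days > 0, is.finite(.data$value))
    # partial edge winters (season-years with < 60 days) distort DJF sums
    if (period != "full_year") agg <- dplyr::filter(agg, .data$n_days >= 60)
    agg
  }

  purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(c("full_year", "DJF", "MAM", "JJA", "SON"), function(period) {
      agg <- aggregate_one(v, rules[[v]], period)
      if (nrow(agg) < 3) {
        warning("skipping ", v, " (", period, "): fewer than 3 years",
                call. = FALSE)
        return(NULL)
      }
      tt <- trend_test(agg$value, time = agg$year - min(agg$year), alpha = alpha)
      tibble(
        variable = v,
        period = period,
        n_years = nrow(agg),
        mean = mean(agg$value),
        sd = sd(agg$value)
      ) %>%
        dplyr::bind_cols(dplyr::select(tt, -"n")) %>%
        dplyr::mutate(stars = dplyr::case_when(
          .data$p_value < 0.01 ~ "**",
          .data$p_value < 0.05 ~ "*",
          TRUE ~ ""
        ))
    })
  })
}

#' Classify a per-DOY NEE trend into the six source/sink categories
#'
#' Uses the Theil-Sen fit evaluated at the first and last year
#' (`f1 = intercept`, `f2 = intercept + slope * (n - 1)` on the 0-based year
#' index). If the fitted values change sign the day is a switch
#' (`switch-to-sink` when the trend ends negative, `switch-to-source` when it
#' ends positive); otherwise the category combines the sign of the mean NEE
#' with the sign of the slope: positive mean and positive slope =
#' `source-larger`, positive mean and negative slope = `source-smaller`,
#' negative mean and negative slope = `sink-larger`, negative mean and
#' positive slope = `sink-smaller`. Zero slope and zero mean give `none`.
#'
#' @param mean_nee Across-year mean of (smoothed) daily NEE for the day.
#' @param trend One-row trend tibble from [trend_test()].
#' @param span Number of years the trend covers.
#' @return A category string.
#' @export
classify_doy_trend <- function(mean_nee, trend, span) {
  slope <- trend$sen_slope
  f1 <- trend$sen_intercept
  f2 <- trend$sen_intercept + slope * (span - 1)
  if (slope == 0 && mean_nee == 0) return("none")
  if (sign(f1) != sign(f2) && sign(f1) != 0 && sign(f2) != 0) {
    return(if (f2 < 0) "switch-to-sink" else "switch-to-source")
  }
  if (mean_nee > 0) {
    if (slope > 0) "source-larger" else if (slope < 0) "source-smaller" else "none"
  } else if (mean_nee < 0) {
    if (slope < 0) "sink-larger" else if (slope > 0) "sink-smaller" else "none"
  } else {
    "none"
  }
}

#' Per-day-of-year trends of daily NEE across years
#'
#' Each year's daily series is smoothed within the year (trailing moving
#' average, default 5 days), Feb 29 is dropped so DOY 1-365 align across
#' years, and for every DOY a Mann-Kendall test and Theil-Sen slope are
#' computed across years. The across-year mean of the smoothed values and the
#' six-category classification ([classify_doy_trend()]) are attached.
#'
#' @param daily Multi-year daily NEE table (`date`, `nee`).
#' @param window Smoothing window in days (default 5).
#' @param alignment Moving-average alignment (default trailing).
#' @param alpha Significance level.
#' @param min_years Minimum valid years per DOY (default 10); sparser DOYs
#'   are skipped.
#' @return Tibble with one row per DOY: `doy`, `n_years`, `mean_nee`, trend
#'   columns, `category`, `significant`.
#' @export
doy_trend_analysis <- function(daily, window = 5,
                               alignment = c("trailing", "centered"),
                               alpha = 0.05, min_years = 10) {
  alignment <- match.arg(alignment)
  smoothed <- daily %>%
    dplyr::mutate(
      year = lubridate::year(.data$date),
      leap_day = lubridate::month(.data$date) == 2 & lubridate::mday(.data$date) == 29
    ) %>%
    dplyr::arrange(.data$date) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::mutate(nee_smooth = moving_average(.data$nee, .env$window,
                                              .env$alignment, na_rm = TRUE)) %>%
    dplyr::ungroup() %>%
    dplyr::filter(!.data$leap_day) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::mutate(doy = dplyr::row_number()) %>%   # DOY after leap-day removal
    dplyr::ungroup()

  n_total_years <- length(unique(smoothed$year))
  if (n_total_years < min_years) {
    stop("doy_trend_analysis needs at least ", min_years, " years", call. = FALSE)
  }

  smoothed %>%
    dplyr::filter(.data$doy <= 365) %>%
    dplyr::group_by(.data$doy) %>%
    dplyr::group_modify(function(d, key) {
      d <- dplyr::filter(d, !is.na(.data$nee_smooth))
      if (nrow(d) < min_years) return(tibble())
      tt <- trend_test(d$nee_smooth, time = d$year - min(d$year), alpha = alpha)
      m <- mean(d$nee_smooth)
      tibble(
        n_years = nrow(d),
        mean_nee = m,
        category = classify_doy_trend(m, tt, span = max(d$year) - min(d$year) + 1)
      ) %>% dplyr::bind_cols(dplyr::select(tt, -"n"))
    }) %>%
    dplyr::ungroup()
}

#' Trends in annual percentiles of daily NEE
#'
#' Per year, the stated percentiles of the unsmoothed daily NEE are computed
#' with the linear-interpolation quantile definition, then each percentile
#' series is tested for a monotonic trend across years.
#'
#' @param daily Multi-year daily NEE table (`date`, `nee`).
#' @param percentiles Percentiles in percent (default `c(1, 5, 50, 95, 99)`).
#' @param min_days Minimum valid days per year (default 300); sparser years
#'   are dropped.
#' @param alpha Significance level.
#' @return Tibble with one row per percentile and the trend columns.
#' @export
percentile_trends <- function(daily, percentiles = c(1, 5, 50, 95, 99),
                              min_days = 300, alpha = 0.05) {
  yearly <- daily %>%
    dplyr::mutate(year = lubridate::year(.data$date)) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::filter(sum(!is.na(.data$nee)) >= min_days) %>%
    dplyr::summarise(
      q = list(quantile(.data$nee, probs = .env$percentiles / 100,
                        na.rm = TRUE, type = 7, names = FALSE)),
      .groups = "drop"
    ) %>%
    tidyr::unnest_wider("q", names_sep = "_") %>%
    stats::setNames(c("year", paste0("p", percentiles)))

  purrr::map_dfr(percentiles, function(p) {
    v <- yearly[[paste0("p", p)]]
    tibble(percentile = p) %>%
      dplyr::bind_cols(trend_test(v, time = yearly$year - min(yearly$year),
                                  alpha = alpha))
  })
}
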