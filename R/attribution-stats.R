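#' Mean daily driver contributions over the study period
#'
#' For every day of year (1-365, Feb 29 dropped) and feature, the mean SHAP
#' value across years. Availability windows restrict individual features to
#' the years their sensor existed (e.g. soil moisture from 2007): pass a
#' named list mapping feature name to its first valid year.
#'
#' @param attr An [compute_attributions()] result.
#' @param availability Named list `feature -> first valid year` (optional).
#' @return Tibble `doy`, `feature`, `mean_shap`, `n_years`.
#' @export
mean_daily_attribution <- function(attr, availability = list()) {
  long <- tidy.nee_attribution(attr) %>%
    dplyr::mutate(
      year = lubridate::year(.data$date),
      leap_day = lubridate::month(.data$date) == 2 &
        lubridate::mday(.data$date) == 29
    ) %>%
    dplyr::filter(!.data$leap_day) %>%
    dplyr::group_by(.data$year, .data$feature) %>%
    dplyr::arrange(.data$date, .by_group = TRUE) %>%
    dplyr::mutate(doy = match(.data$date, unique(.data$date))) %>%
    dplyr::ungroup()
  if (length(availability)) {
    keep <- purrr::map2_lgl(
      long$feature, long$year,
      function(f, y) is.null(availability[[f]]) || y >= availability[[f]]
    )
    long <- long[keep, ]
  }
  long %>%
    dplyr::filter(.data$doy <= 365, !is.na(.data$shap)) %>%
    dplyr::group_by(.data$doy, .data$feature) %>%
    dplyr::summarise(
      mean_shap = mean(.data$shap),
      n_years = dplyr::n(),
      .groups = "drop"
    )
}

#' Feature-value ranges that favor net carbon uptake
#'
#' Bins the feature's observed values into `n_bins` equal-count bins, takes
#' the mean SHAP value per bin, and merges contiguous runs of bins with mean
#' SHAP < 0 into intervals. Within these ranges the feature, on average,
#' pushed the modeled NEE toward uptake. Interval edges are reported as bin
#' boundaries.
#'
#' @param attr An [compute_attributions()] result.
#' @param features The feature matrix the attributions were computed on
#'   (source of the raw feature values).
#' @param feature Feature name.
#' @param n_bins Number of equal-count bins (default 50).
#' @param min_obs Minimum paired observations required (default 500).
#' @return Tibble of intervals: `lower`, `upper`, `n_bins_merged`,
#'   `mean_shap` (observation-weighted across the merged bins). Zero rows if
#'   the mean SHAP is nowhere negative.
#' @export
favorable_ranges <- function(attr, features, feature, n_bins = 50,
                             min_obs = 500) {
  if (!feature %in% attr(attr, "feature_names")) {
    stop("unknown feature: ", feature, call. = FALSE)
  }
  d <- tibble(
    value = features[[feature]][match(attr$date, features$date)],
    shap = as_tibble(attr)[[feature]]
  ) %>%
    dplyr::filter(!is.na(.data$value), !is.na(.data$shap))
  if (nrow(d) < min_obs) {
    stop("need at least ", min_obs, " observations for ", feature,
         call. = FALSE)
  }
  breaks <- unique(quantile(d$value, probs = seq(0, 1, length.out = n_bins + 1),
                            type = 7, names = FALSE))
  d$bin <- cut(d$value, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  per_bin <- d %>%
    dplyr::group_by(.data$bin) %>%
    dplyr::summarise(mean_shap = mean(.data$shap), n = dplyr::n(),
                     .groups = "drop") %>%
    dplyr::arrange(.data$bin) %>%
    dplyr::mutate(
      lower = breaks[.data$bin],
      upper = breaks[.data$bin + 1L],
      negative = .data$mean_shap < 0
    )
  runs <- rle(per_bin$negative)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  purrr::map_dfr(which(runs$values), function(k) {
    rows <- per_bin[starts[k]:ends[k], ]
    tibble(
      feature = feature,
      lower = min(rows$lower),
      upper = max(rows$upper),
      n_bins_merged = nrow(rows),
      mean_shap = sum(rows$mean_shap * rows$n) / sum(rows$n)
    )
  })
}

#' Driver shifts around the start and end of the uptake season
#'
#' For each year and feature, the difference between the median SHAP value
#' over the 10 days *after* a transition (days +1..+10) and the 10 days
#' *before* it (days -10..-1), the transition day itself excluded; the final
#' statistic is the median of these differences across years. Negative values
#' mean the feature's contribution to NEE decreased after the transition
#' (pushed toward uptake after SOS); positive values mean it increased.
#' Years lacking a defined transition or a full window on either side are
#' skipped with a warning.
#'
#' @param attr An [compute_attributions()] result.
#' @param phenology Per-year phenology tibble ([extract_cup_all()]).
#' @param window Days on each side (default 10).
#' @return Tibble `transition` (`"sos"`/`"eos"`), `feature`, `median_shift`,
#'   `n_years`.
#' @export
sos_eos_driver_shift <- function(attr, phenology, window = 10) {
  feats <- attr(attr, "feature_names")
  wide <- as_tibble(attr)
  shift_one <- function(transition_doy_col, label) {
    rows <- dplyr::filter(phenology, !.data$no_cup,
                          !is.na(.data[[transition_doy_col]]))
    per_year <- purrr::pmap_dfr(
      list(rows$year, rows[[transition_doy_col]]),
      function(yr, doy) {
        t_date <- as.Date(sprintf("%d-01-01", yr)) + doy - 1
        before <- wide[wide$date %in% (t_date - seq_len(window)), feats, drop = FALSE]
        after <- wide[wide$date %in% (t_date + seq_len(window)), feats, drop = FALSE]
        if (nrow(before) < window || nrow(after) < window ||
            anyNA(before) || anyNA(after)) {
          warning("skipping year ", yr, " (", label,
                  "): incomplete attribution window", call. = FALSE)
          return(NULL)
        }
        tibble(
          year = yr,
          feature = feats,
          delta = purrr::map_dbl(feats, function(f) {
            median(after[[f]]) - median(before[[f]])
          })
        )
      }
    )
    if (nrow(per_year) == 0) return(NULL)
    per_year %>%
      dplyr::group_by(.data$feature) %>%
      dplyr::summarise(
        transition = label,
        median_shift = median(.data$delta),
        n_years = dplyr::n(),
        .groups = "drop"
      )
  }
  dplyr::bind_rows(
    shift_one("sos_doy", "sos"),
    shift_one("eos_doy", "eos")
  ) %>%
    dplyr::select("transition", "feature", "median_shift", "n_years")
}

#' Long-term trends in seasonal driver contributions
#'
#' Per feature: the mean SHAP value within the chosen climatological season
#' for each season-year, then a Mann-Kendall test and Theil-Sen slope across
#' years.
#'
#' @param attr An [compute_attributions()] result.
#' @param season One of `"DJF"`, `"MAM"`, `"JJA"`, `"SON"`.
#' @param alpha Significance level.
#' @param min_years Minimum season-years required (default 10).
#' @return Tibble with one row per feature and the trend columns.
#' @export
seasonal_attribution_trends <- function(attr, season = "JJA", alpha = 0.05,
                                        min_years = 10) {
  season <- match.arg(season, c("DJF", "MAM", "JJA", "SON"))
  long <- tidy.nee_attribution(attr)
  seas <- assign_season(long$date)
  long$season <- seas$season
  long$season_year <- seas$season_year
  yearly <- long %>%
    dplyr::filter(.data$season == .env$season, !is.na(.data$shap)) %>%
    dplyr::group_by(.data$feature, .data$season_year) %>%
    dplyr::summarise(mean_shap = mean(.data$shap), .groups = "drop")
  purrr::map_dfr(unique(yearly$feature), function(f) {
    d <- dplyr::filter(yearly, .data$feature == f)
    if (nrow(d) < min_years) return(NULL)
    tibble(feature = f, season = season) %>%
      dplyr::bind_cols(trend_test(d$mean_shap,
                                  time = d$season_year - min(d$season_year),
                                  alpha = alpha))
  })
}

#' Strongest interacting feature (descriptive)
#'
#' For a focal feature, finds the other feature whose binned values most
#' reduce the variance of the focal feature's SHAP values (largest relative
#' drop from total variance to the observation-weighted mean of within-bin
#' variances). Descriptive only; it does not estimate interaction SHAP
#' values.
#'
#' @param attr An [compute_attributions()] result.
#' @param features Feature matrix with the raw values.
#' @param feature Focal feature name.
#' @param n_bins Bins for the candidate features (default 10).
#' @return Tibble of candidates sorted by `variance_reduction` (first row is
#'   the strongest interactor).
#' @export
strongest_interaction <- function(attr, features, feature, n_bins = 10) {
  feats <- attr(attr, "feature_names")
  shap <- as_tibble(attr)[[feature]]
  idx <- match(attr$date, features$date)
  total_var <- stats::var(shap, na.rm = TRUE)
  purrr::map_dfr(setdiff(feats, feature), function(g) {
    v <- features[[g]][idx]
    ok <- !is.na(v) & !is.na(shap)
    if (sum(ok) < 10 * n_bins) return(NULL)
    br <- unique(quantile(v[ok], probs = seq(0, 1, length.out = n_bins + 1),
                          names = FALSE))
    if (length(br) < 3) return(NULL)
    bin <- cut(v[ok], breaks = br, include.lowest = TRUE, labels = FALSE)
    within <- tapply(shap[ok], bin, stats::var)
    wts <- tapply(shap[ok], bin, length)
    wvar <- sum(within * wts, na.rm = TRUE) / sum(wts[!is.na(within)])
    tibble(candidate = g, variance_reduction = 1 - wvar / total_var)
  }) %>%
    dplyr::arrange(dplyr::desc(.data$variance_reduction))
}
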