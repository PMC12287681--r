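#' Extract the net carbon uptake period (CUP) from one year of daily NEE
#'
#' The daily NEE series (micrometeorological sign convention: negative =
#' net uptake) is smoothed with a moving average (default 10-day trailing,
#' truncated at the year edges so the first days of January are valid
#' candidates). The start of season (SOS) is the earliest day of year on which
#' the smoothed series becomes negative *and* stays negative for at least
#' `persistence` consecutive days including the SOS day itself; the end of
#' season (EOS) is the latest day that is negative and was preceded by at
#' least `persistence` consecutive negative days including itself. A candidate
#' failing its persistence criterion is discarded together with its whole
#' contiguous negative run, and the search continues with the next run. A
#' smoothed value of exactly 0 counts as non-negative. If no candidate
#' qualifies the year is flagged as having no CUP.
#'
#' Release/uptake day counts are taken from the *unsmoothed* series:
#' `n_release_days_within` counts days in `[SOS, EOS]` with NEE > 0,
#' `n_uptake_days_outside` counts days outside with NEE < 0.
#'
#' @param daily Data frame with columns `date` (Date) and `nee`
#'   (g C m^-2 d^-1), covering a single calendar year.
#' @param window Smoothing window in days (default 10).
#' @param alignment Moving-average alignment, `"trailing"` (default) or
#'   `"centered"`.
#' @param persistence Required run of negative smoothed days (default 14).
#' @param min_coverage Minimum number of non-missing days required (default
#'   300).
#' @return One-row tibble: `year`, `sos_doy`, `eos_doy`, `cup_length`
#'   (inclusive, `EOS - SOS + 1`), `n_release_days_within`,
#'   `n_uptake_days_outside`, `pct_release_within`, `pct_uptake_outside`,
#'   `no_cup` flag.
#' @examples
#' yr <- tibble::tibble(
#'   date = seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
#' )
#' yr$nee <- ifelse(seq_len(nrow(yr)) %in% 100:250, -1, 1)
#' extract_cup(yr)
#' @export
extract_cup <- function(daily, window = 10,
                        alignment = c("trailing", "centered"),
                        persistence = 14, min_coverage = 300) {
  alignment <- match.arg(alignment)
  stopifnot(is.data.frame(daily), all(c("date", "nee") %in% names(daily)))
  years <- unique(lubridate::year(daily$date))
  if (length(years) != 1) {
    stop("extract_cup expects a single calendar year; got ",
         paste(years, collapse = ", "), call. = FALSE)
  }
  daily <- dplyr::arrange(daily, .data$date)
  if (sum(!is.na(daily$nee)) < min_coverage) {
    stop("year ", years, " has fewer than ", min_coverage,
         " non-missing days", call. = FALSE)
  }
  smoothed <- moving_average(daily$nee, window, alignment, na_rm = TRUE)
  doy <- lubridate::yday(daily$date)
  neg <- !is.na(smoothed) & smoothed < 0

  runs <- negative_runs(neg)
  sos_idx <- NA_integer_
  for (k in seq_len(nrow(runs))) {          # earliest run long enough
    if (runs$length[k] >= persistence) { sos_idx <- runs$start[k]; break }
  }
  eos_idx <- NA_integer_
  for (k in rev(seq_len(nrow(runs)))) {     # latest run long enough
    if (runs$length[k] >= persistence) { eos_idx <- runs$end[k]; break }
  }

  no_cup <- is.na(sos_idx) || is.na(eos_idx)
  sos <- if (no_cup) NA_integer_ else doy[sos_idx]
  eos <- if (no_cup) NA_integer_ else doy[eos_idx]
  cup_length <- if (no_cup) NA_integer_ else eos - sos + 1L

  nee <- daily$nee
  if (no_cup) {
    within <- rep(FALSE, length(nee))
  } else {
    within <- doy >= sos & doy <= eos
  }
  n_release_within <- sum(within & !is.na(nee) & nee > 0)
  n_uptake_outside <- sum(!within & !is.na(nee) & nee < 0)
  n_within <- sum(within & !is.na(nee))
  n_outside <- sum(!within & !is.na(nee))

  tibble(
    year = years,
    sos_doy = sos,
    eos_doy = eos,
    cup_length = cup_length,
    n_release_days_within = n_release_within,
    n_uptake_days_outside = n_uptake_outside,
    pct_release_within = if (n_within > 0) 100 * n_release_within / n_within else NA_real_,
    pct_uptake_outside = if (n_outside > 0) 100 * n_uptake_outside / n_outside else NA_real_,
    no_cup = no_cup
  )
}

# contiguous runs of TRUE in a logical vector, as (start, end, length) rows
negative_runs <- function(neg) {
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

#' Extract the CUP for every year of a multi-year daily series
#'
#' Maps [extract_cup()] over calendar years; years with insufficient coverage
#' or errors are skipped with a warning.
#'
#' @inheritParams extract_cup
#' @return Tibble with one row per successfully processed year.
#' @export
extract_cup_all <- function(daily, window = 10,
                            alignment = c("trailing", "centered"),
                            persistence = 14, min_coverage = 300) {
  alignment <- match.arg(alignment)
  daily %>%
    dplyr::mutate(.year = lubridate::year(.data$date)) %>%
    dplyr::group_split(.data$.year) %>%
    purrr::map(function(d) {
      tryCatch(
        extract_cup(dplyr::select(d, -".year"), window, alignment,
                    persistence, min_coverage),
        error = function(e) {
          warning(conditionMessage(e), call. = FALSE)
          NULL
        }
      )
    }) %>%
    purrr::compact() %>%
    dplyr::bind_rows()
}

#' Summarise per-year phenology: means, extremes and long-term trends
#'
#' @param results Tibble of per-year phenology rows from [extract_cup_all()].
#' @param alpha Significance level for the trend tests.
#' @return Tibble with one row per metric (`sos_doy`, `eos_doy`, `cup_length`):
#'   mean, sd, min/max with their years, and Mann-Kendall + Theil-Sen trend
#'   columns across years.
#' @export
cup_summary <- function(results, alpha = 0.05) {
  defined <- dplyr::filter(results, !.data$no_cup)
  if (nrow(defined) < 1) stop("no years with a defined CUP", call. = FALSE)
  purrr::map_dfr(c("sos_doy", "eos_doy", "cup_length"), function(metric) {
    v <- defined[[metric]]
    yrs <- defined$year
    base <- tibble(
      metric = metric,
      n_years = length(v),
      mean = mean(v),
      sd = sd(v),
      min = min(v),
      min_year = yrs[which.min(v)],
      max = max(v),
      max_year = yrs[which.max(v)]
    )
    if (length(v) >= 3) {
      dplyr::bind_cols(base, trend_test(v, time = yrs - min(yrs), alpha = alpha))
    } else {
      base
    }
  })
}

#' Regressions of annual NEE on phenology metrics
#'
#' For each of CUP length, SOS and EOS against annual cumulative NEE:
#' ordinary least-squares slope/intercept, R^2, the two-sided p-value on the
#' slope, and the Spearman rank correlation.
#'
#' @param annual_nee Data frame with columns `year` and `nee_annual`
#'   (g C m^-2 yr^-1).
#' @param results Per-year phenology tibble ([extract_cup_all()]).
#' @return Tibble, one row per metric, with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `spearman_rho`, `n`. Metrics with degenerate variance are
#'   returned with `degenerate = TRUE` and missing statistics.
#' @export
phenology_nee_relationships <- function(annual_nee, results) {
  joined <- dplyr::inner_join(
    annual_nee,
    dplyr::filter(results, !.data$no_cup),
    by = "year"
  )
  if (nrow(joined) < 4) stop("need at least 4 paired years", call. = FALSE)
  purrr::map_dfr(c("cup_length", "sos_doy", "eos_doy"), function(metric) {
    x <- as.numeric(joined[[metric]])
    y <- joined$nee_annual
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(metric = metric, n = length(x), degenerate = TRUE,
                    slope = NA_real_, intercept = NA_real_,
                    r_squared = NA_real_, p_value = NA_real_,
                    spearman_rho = NA_real_))
    }
    fit <- lm(y ~ x)
    sfit <- summary(fit)
    tibble(
      metric = metric,
      n = length(x),
      degenerate = FALSE,
      slope = coef(fit)[[2]],
      intercept = coef(fit)[[1]],
      r_squared = sfit$r.squared,
      p_value = sfit$coefficients[2, 4],
      spearman_rho = cor(x, y, method = "spearman")
    )
  })
}
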