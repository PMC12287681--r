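#' Default predictor set for the daily-NEE driver model
#'
#' 21 features assembled from the met-driver table: the raw daily variables
#' plus smoothed (trailing moving average, MA), cumulative (trailing moving
#' sum, MS) and lagged versions that capture sustained temperature passages,
#' antecedent cold sums, and radiation/temperature memory at 180- and 365-day
#' lags. The set is a package default; override it with your own spec tibble
#' or a YAML file ([feature_specs_from_yaml()]).
#'
#' @return Tibble with columns `name`, `base_variable`, `transform`
#'   (`none`/`moving_average`/`moving_sum`), `window`, `lag`.
#' @export
default_feature_specs <- function() {
  tibble::tribble(
    ~name,                      ~base_variable,   ~transform,        ~window, ~lag,
    "t_air_mean",               "t_air_mean",     "none",            1L,      0L,
    "t_air_min",                "t_air_min",      "none",            1L,      0L,
    "t_air_max",                "t_air_max",      "none",            1L,      0L,
    "t_air_mean_ma3",           "t_air_mean",     "moving_average",  3L,      0L,
    "t_air_min_ma5",            "t_air_min",      "moving_average",  5L,      0L,
    "hours_below_0",            "hours_below_0",  "none",            1L,      0L,
    "t_below0_ms15_lag15",      "hours_below_0",  "moving_sum",      15L,     15L,
    "rg",                       "rg",             "none",            1L,      0L,
    "rg_ma30",                  "rg",             "moving_average",  30L,     0L,
    "rg_ma30_lag180",           "rg",             "moving_average",  30L,     180L,
    "t_air_mean_ma30_lag180",   "t_air_mean",     "moving_average",  30L,     180L,
    "t_air_mean_ma30_lag365",   "t_air_mean",     "moving_average",  30L,     365L,
    "swc",                      "swc",            "none",            1L,      0L,
    "swc_ma15",                 "swc",            "moving_average",  15L,     0L,
    "ppfd",                     "ppfd",           "none",            1L,      0L,
    "daylength",                "daylength",      "none",            1L,      0L,
    "prec",                     "prec",           "none",            1L,      0L,
    "prec_ms15",                "prec",           "moving_sum",      15L,     0L,
    "rh",                       "rh",             "none",            1L,      0L,
    "vpd",                      "vpd",            "none",            1L,      0L,
    "vpd_ma3",                  "vpd",            "moving_average",  3L,      0L
  )
}

#' Read a feature-spec table from YAML
#'
#' The YAML is a list of entries with fields `name`, `base_variable`,
#' `transform`, `window`, `lag` (window/lag optional, defaulting to 1/0).
#'
#' @param path Path to the YAML file.
#' @return A feature-spec tibble as in [default_feature_specs()].
#' @export
feature_specs_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  purrr::map_dfr(y, function(e) {
    tibble(
      name = e$name,
      base_variable = e$base_variable,
      transform = e$transform %||% "none",
      window = as.integer(e$window %||% 1L),
      lag = as.integer(e$lag %||% 0L)
    )
  })
}

# rolling statistic over the previous `window` days including the current
# one; full windows only (leading rows and windows containing NA give NA)
roll_full <- function(x, window, fun) {
  n <- length(x)
  if (window == 1L) return(x)
  out <- rep(NA_real_, n)
  if (n >= window) {
    for (i in window:n) out[i] <- fun(x[(i - window + 1L):i])
  }
  out
}

#' Build the lag/moving-window feature matrix
#'
#' Applies each feature spec to the met table: the window statistic first
#' (trailing over the previous `window` days including the current day; full
#' windows only, so leading rows lacking history are missing), then the lag
#' shift (day *d* sees the transformed value of day *d - lag*). Transforms
#' cross calendar-year boundaries, so the met table must be continuous in
#' time. Predictor missingness (e.g. soil moisture before its sensor start)
#' is passed through.
#'
#' @param met Continuous met-driver table (one row per day, `date` plus the
#'   base variables).
#' @param specs Feature-spec tibble (default [default_feature_specs()]);
#'   specs whose base variable is absent from `met` are dropped with a
#'   warning.
#' @param daily Optional daily NEE table (`date`, `nee`); when supplied, the
#'   target column `nee` is joined in and rows with a missing target are
#'   dropped.
#' @return Tibble `date` + one column per feature (+ `nee` if `daily` given).
#' @export
build_features <- function(met, specs = default_feature_specs(), daily = NULL) {
  stopifnot("date" %in% names(met))
  met <- dplyr::arrange(met, .data$date)
  if (any(diff(as.integer(met$date)) != 1L)) {
    stop("met table must be continuous in time (one row per day)", call. = FALSE)
  }
  missing_base <- setdiff(unique(specs$base_variable), names(met))
  if (length(missing_base)) {
    stop("unknown base variable(s): ", paste(missing_base, collapse = ", "),
         call. = FALSE)
  }
  bad_tr <- setdiff(unique(specs$transform),
                    c("none", "moving_average", "moving_sum"))
  if (length(bad_tr)) {
    stop("unknown transform(s): ", paste(bad_tr, collapse = ", "), call. = FALSE)
  }
  out <- tibble(date = met$date)
  for (k in seq_len(nrow(specs))) {
    s <- specs[k, ]
    x <- met[[s$base_variable]]
    x <- switch(s$transform,
      none = x,
      moving_average = roll_full(x, s$window, mean),
      moving_sum = roll_full(x, s$window, sum)
    )
    if (s$lag > 0) x <- dplyr::lag(x, s$lag)
    out[[s$name]] <- x
  }
  if (!is.null(daily)) {
    out <- out %>%
      dplyr::inner_join(dplyr::select(daily, "date", "nee"), by = "date") %>%
      dplyr::filter(!is.na(.data$nee))
  }
  out
}
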