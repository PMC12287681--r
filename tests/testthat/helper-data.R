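# shared fixture builders -----------------------------------------------

# one non-leap calendar year of daily NEE from a vector (recycled/truncated)
make_daily_year <- function(nee, year = 2018) {
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  tibble::tibble(date = dates, nee = rep_len(nee, length(dates)))
}

# multi-year daily table from a year x 365 matrix; Feb 29 is omitted so
# every year contributes exactly 365 aligned days
make_daily_matrix <- function(mat, start_year = 1997) {
  years <- start_year + seq_len(nrow(mat)) - 1
  purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    dates <- seq(as.Date(sprintf("%d-01-01", years[i])),
                 as.Date(sprintf("%d-12-31", years[i])), by = "day")
    dates <- dates[!(lubridate::month(dates) == 2 & lubridate::mday(dates) == 29)]
    tibble::tibble(date = dates, nee = mat[i, ])
  })
}

# brute-force Mann-Kendall S and tau by explicit double loop
oracle_mk_s <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  list(s = s, tau = s / (n * (n - 1) / 2))
}

# exhaustive-search CUP oracle: earliest day starting `persistence`
# consecutive negative smoothed days, and latest day ending such a run
oracle_cup <- function(nee, window, persistence) {
  sm <- fluxphen::moving_average(nee, window, "trailing")
  n <- length(sm)
  sos <- NA_integer_
  for (d in seq_len(n - persistence + 1)) {
    if (all(sm[d:(d + persistence - 1)] < 0)) { sos <- d; break }
  }
  eos <- NA_integer_
  for (d in n:persistence) {
    if (all(sm[(d - persistence + 1):d] < 0)) { eos <- d; break }
  }
  list(sos = sos, eos = eos)
}

# small fast scenario for driver-model tests
small_scenario <- function(n_years = 6, seed = 7, ...) {
  fluxphen::flux_scenario(n_years = n_years, start_year = 2001,
                          seed = seed, ...)
}

# percentile-bootstrap CI for the Theil-Sen slope
sen_bootstrap_ci <- function(y, n_boot = 400, level = 0.95) {
  t0 <- seq_along(y) - 1
  slopes <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(y), replace = TRUE)
    if (length(unique(t0[idx])) < 2) return(NA_real_)
    fluxphen::theil_sen(y[idx], time = t0[idx])$sen_slope
  }, numeric(1))
  stats::quantile(slopes, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
}
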