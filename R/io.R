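#' Read a half-hourly flux CSV (FLUXNET/ICOS dialect)
#'
#' Expects `TIMESTAMP_START`/`TIMESTAMP_END` columns in `YYYYMMDDHHMM` local
#' standard time and a `-9999` sentinel for missing values. Column names can
#' be remapped via `columns` (internal name -> file name), e.g. when the NEE
#' column is called `NEE_VUT_REF`.
#'
#' @param path Path to the CSV file.
#' @param columns Named character vector mapping internal names
#'   (`nee`, `random_uncertainty`, `nee_ustar_low`, `nee_ustar_high`) to file
#'   column names. Only `nee` is required in the file.
#' @param sentinel Missing-value sentinel (default `-9999`).
#' @param strict If `TRUE` (default), non-monotone or non-30-minute timestamps
#'   are an error; unknown columns are an error too.
#' @return Tibble with `timestamp_start`, `timestamp_end` (POSIXct, UTC-naive
#'   local time), `nee` (umol CO2 m^-2 s^-1) and any optional uncertainty /
#'   u*-scenario columns present.
#' @export
read_halfhourly_csv <- function(path,
                                columns = c(nee = "NEE"),
                                sentinel = -9999,
                                strict = TRUE) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (ts_col in c("TIMESTAMP_START", "TIMESTAMP_END")) {
    if (!ts_col %in% names(raw)) {
      stop("missing required column ", ts_col, call. = FALSE)
    }
  }
  if (!"nee" %in% names(columns)) {
    stop("`columns` must map an internal `nee` column", call. = FALSE)
  }
  missing_cols <- setdiff(unname(columns["nee"]), names(raw))
  if (length(missing_cols)) {
    stop("file lacks mapped column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  known <- c("TIMESTAMP_START", "TIMESTAMP_END", unname(columns))
  if (strict) {
    extra <- setdiff(names(raw), known)
    if (length(extra)) {
      stop("unknown columns under strict mode: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  parse_ts <- function(v) {
    out <- lubridate::ymd_hm(as.character(v), tz = "UTC", quiet = TRUE)
    if (any(is.na(out))) stop("malformed timestamp(s) in ", path, call. = FALSE)
    out
  }
  out <- tibble(
    timestamp_start = parse_ts(raw$TIMESTAMP_START),
    timestamp_end = parse_ts(raw$TIMESTAMP_END)
  )
  for (nm in names(columns)) {
    col <- columns[[nm]]
    if (col %in% names(raw)) {
      v <- as.numeric(raw[[col]])
      v[v == sentinel] <- NA_real_
      out[[nm]] <- v
    }
  }
  if (strict) {
    dt <- diff(as.numeric(out$timestamp_start))
    if (any(dt <= 0)) stop("timestamps are not strictly increasing", call. = FALSE)
    if (any(dt != 1800)) stop("timestamps are not on a 30-minute grid", call. = FALSE)
  }
  out
}

#' Aggregate half-hourly NEE to daily cumulative carbon sums
#'
#' Converts umol CO2 m^-2 s^-1 to g C m^-2 d^-1 via
#' `sum(flux * 1800 s) * 12.0107e-6 g C umol^-1` over the 48 half-hours of
#' each day (day boundaries at 00:00 local standard time). A day with any
#' missing half-hour, or with fewer than 48 records, yields a missing daily
#' value — inputs are expected gap-filled, so incompleteness flags upstream
#' problems. The number of incomplete days is attached as attribute
#' `n_incomplete_days` and reported via a message.
#'
#' @param records Tibble from [read_halfhourly_csv()] (needs
#'   `timestamp_start` and `nee`).
#' @return Tibble with `date` and `nee` (g C m^-2 d^-1).
#' @export
aggregate_daily <- function(records) {
  stopifnot(all(c("timestamp_start", "nee") %in% names(records)))
  out <- records %>%
    dplyr::mutate(date = lubridate::as_date(.data$timestamp_start)) %>%
    dplyr::group_by(.data$date) %>%
    dplyr::summarise(
      complete = dplyr::n() == 48L && !anyNA(.data$nee),
      nee = sum(.data$nee) * 1800 * GC_PER_UMOL,
      .groups = "drop"
    ) %>%
    dplyr::mutate(nee = ifelse(.data$complete, .data$nee, NA_real_)) %>%
    dplyr::select("date", "nee")
  n_bad <- sum(is.na(out$nee))
  if (n_bad > 0) message(n_bad, " incomplete day(s) set to missing")
  attr(out, "n_incomplete_days") <- n_bad
  out
}

#' Aggregate daily random uncertainty and u*-threshold spread to annual values
#'
#' The annual random component adds daily random errors in quadrature
#' (independence assumption): \eqn{\sigma_{rand} = \sqrt{\sum_d u_d^2}}. The
#' u* component is half the absolute range of annual NEE across the gap-filled
#' series at the 16th/50th/84th-percentile u* thresholds. The joint
#' uncertainty is their quadrature sum.
#'
#' @param daily Data frame with `date` and `random_uncertainty`
#'   (g C m^-2 d^-1).
#' @param annual_ustar Optional data frame with `year` and annual NEE columns
#'   `nee_16`, `nee_50`, `nee_84` (g C m^-2 yr^-1). When absent, the u*
#'   component is 0 and the row is flagged `ustar_missing`.
#' @return Tibble with `year`, `random_component`, `ustar_component`, `joint`
#'   (all g C m^-2 yr^-1) and `ustar_missing`.
#' @export
joint_annual_uncertainty <- function(daily, annual_ustar = NULL) {
  stopifnot(all(c("date", "random_uncertainty") %in% names(daily)))
  rand <- daily %>%
    dplyr::mutate(year = lubridate::year(.data$date)) %>%
    dplyr::group_by(.data$year) %>%
    dplyr::summarise(
      random_component = sqrt(sum(.data$random_uncertainty^2, na.rm = TRUE)),
      .groups = "drop"
    )
  if (is.null(annual_ustar)) {
    warning("no u*-threshold series supplied; joint = random component",
            call. = FALSE)
    return(dplyr::mutate(
      rand,
      ustar_component = 0,
      joint = .data$random_component,
      ustar_missing = TRUE
    ))
  }
  stopifnot(all(c("year", "nee_16", "nee_50", "nee_84") %in% names(annual_ustar)))
  rand %>%
    dplyr::left_join(annual_ustar, by = "year") %>%
    dplyr::rowwise() %>%
    dplyr::mutate(
      ustar_missing = anyNA(c(.data$nee_16, .data$nee_50, .data$nee_84)),
      ustar_component = if (.data$ustar_missing) 0 else {
        (max(c(.data$nee_16, .data$nee_50, .data$nee_84)) -
           min(c(.data$nee_16, .data$nee_50, .data$nee_84))) / 2
      },
      joint = sqrt(.data$random_component^2 + .data$ustar_component^2)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("year", "random_component", "ustar_component", "joint",
                  "ustar_missing")
}

#' Write a daily table as CSV with a JSON provenance sidecar
#'
#' @param x Data frame to write (ISO dates).
#' @param path Output CSV path; the sidecar is written to `<path>.json`.
#' @param provenance Named list recorded alongside (inputs, seed, settings);
#'   package version and timestamp are added.
#' @return `path`, invisibly.
#' @export
write_daily_csv <- function(x, path, provenance = list()) {
  readr::write_csv(x, path)
  meta <- c(
    provenance,
    list(
      package = "fluxphen",
      version = as.character(utils::packageVersion("fluxphen")),
      written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
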