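#' Moving average with trailing or centered alignment
#'
#' Trailing alignment (the default) averages the previous `window` days
#' including the current one, i.e. the value at day *d* is the mean of days
#' `d - window + 1 ... d`. Centered alignment uses a symmetric window; for an
#' even window the extra day is taken from the past side. Windows truncated at
#' the series edges use the available days only, so the output has no missing
#' leading values (contrast [build_features()], whose rolling transforms
#' require full windows).
#'
#' @param x Numeric vector, one value per day. `NA`s propagate: a window mean
#'   is computed over its non-missing days only when `na_rm = TRUE`.
#' @param window Window length in days, `>= 1`.
#' @param alignment `"trailing"` or `"centered"`.
#' @param na_rm Drop missing values within each window (default `FALSE`).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' moving_average(c(1, 2, 3, 4), 3) # trailing, truncated edges
#' @export
moving_average <- function(x, window, alignment = c("trailing", "centered"),
                           na_rm = FALSE) {
  alignment <- match.arg(alignment)
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    stop("`window` must be a single integer >= 1", call. = FALSE)
  }
  window <- as.integer(window)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  if (alignment == "trailing") {
    lo <- pmax(seq_len(n) - window + 1L, 1L)
    hi <- seq_len(n)
  } else {
    # even windows put the extra day on the past side
    back <- ceiling((window - 1L) / 2)
    fwd <- window - 1L - back
    lo <- pmax(seq_len(n) - back, 1L)
    hi <- pmin(seq_len(n) + fwd, n)
  }
  vapply(seq_len(n), function(i) {
    w <- x[lo[i]:hi[i]]
    if (na_rm) w <- w[!is.na(w)]
    if (length(w) == 0L) NA_real_ else mean(w)
  }, numeric(1))
}
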