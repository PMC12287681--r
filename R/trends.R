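#' Mann-Kendall test for a monotonic trend
#'
#' Computes the Mann-Kendall statistic
#' \eqn{S = \sum_{i<j} \mathrm{sign}(x_j - x_i)} over the series in time order,
#' its tie-corrected variance
#' \eqn{Var(S) = [n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)]/18} (sum over tied
#' groups of size t), the continuity-corrected normal score
#' \eqn{z = (S \mp 1)/\sqrt{Var(S)}}, a two-sided p-value from the normal
#' approximation, and Kendall's \eqn{\tau = S / (n(n-1)/2)}.
#'
#' Missing values are removed (with their time points) before testing; the
#' statistic depends only on the rank order of the remaining values, so it is
#' invariant under strictly monotone transforms.
#'
#' @param x Numeric vector in time order; `NA`s dropped.
#' @param alpha Two-sided significance level for the `significant` flag.
#' @return One-row tibble with columns `n`, `s_statistic`, `var_s`, `z`,
#'   `p_value`, `tau`, `significant`.
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 6, 5, 8, 9))
#' @export
mann_kendall <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("mann_kendall needs at least 3 non-missing values", call. = FALSE)
  d <- sign(outer(x, x, "-"))
  s <- sum(d[lower.tri(d)])        # [i,j] with i > j holds sign(x_i - x_j), i later
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) - sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (s > 0) {
    (s - 1) / sqrt(var_s)
  } else if (s < 0) {
    (s + 1) / sqrt(var_s)
  } else {
    0
  }
  if (var_s == 0) z <- 0           # all values tied
  p <- 2 * pnorm(-abs(z))
  tibble(
    n = n,
    s_statistic = s,
    var_s = var_s,
    z = z,
    p_value = p,
    tau = s / (n * (n - 1) / 2),
    significant = p < alpha
  )
}

#' Theil-Sen slope and intercept
#'
#' Slope is the median of all pairwise slopes
#' \eqn{(x_j - x_i)/(t_j - t_i)} over \eqn{i < j}; the intercept is
#' \eqn{\mathrm{median}(x_i - \hat\beta t_i)}. By default time is the 0-based
#' observation index, so the intercept is the fitted level at the first
#' observation.
#'
#' @param x Numeric vector in time order; `NA`s dropped with their times.
#' @param time Numeric time points (default `0, 1, ..., n-1`).
#' @return One-row tibble with `sen_slope` and `sen_intercept`.
#' @examples
#' theil_sen(3 * (0:9) + 2)
#' @export
theil_sen <- function(x, time = seq_along(x) - 1) {
  stopifnot(length(time) == length(x))
  keep <- !is.na(x) & !is.na(time)
  x <- x[keep]; time <- time[keep]
  n <- length(x)
  if (n < 2 || length(unique(time)) < 2) {
    stop("theil_sen needs at least 2 distinct time points", call. = FALSE)
  }
  ij <- utils::combn(n, 2)
  dt <- time[ij[2, ]] - time[ij[1, ]]
  ok <- dt != 0
  slope <- median((x[ij[2, ]] - x[ij[1, ]])[ok] / dt[ok])
  tibble(sen_slope = slope, sen_intercept = median(x - slope * time))
}

#' Combined Mann-Kendall + Theil-Sen trend fit
#'
#' Convenience wrapper returning the full trend record used throughout the
#' package: Mann-Kendall test plus Theil-Sen slope/intercept on a 0-based
#' time index (or supplied times, e.g. calendar years).
#'
#' @inheritParams theil_sen
#' @inheritParams mann_kendall
#' @return One-row tibble combining [mann_kendall()] and [theil_sen()] columns.
#' @export
trend_test <- function(x, time = seq_along(x) - 1, alpha = 0.05) {
  keep <- !is.na(x)
  dplyr::bind_cols(
    mann_kendall(x[keep], alpha = alpha),
    theil_sen(x[keep], time = time[keep])
  )
}

#' Pettitt change-point test
#'
#' Nonparametric single change-point test:
#' \eqn{U_t = \sum_{i \le t} \sum_{j > t} \mathrm{sign}(x_j - x_i)}, the change
#' point is \eqn{\arg\max_t |U_t|} and the approximate significance is
#' \eqn{p \approx 2 \exp(-6 K^2 / (n^3 + n^2))} with \eqn{K = \max_t |U_t|},
#' capped at 1.
#'
#' @param x Numeric vector in time order, `n >= 8` after dropping `NA`s.
#' @return One-row tibble with `n`, `changepoint` (index of the last
#'   observation of the first segment), `k_statistic`, `p_value`.
#' @export
pettitt_changepoint <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8) stop("pettitt_changepoint needs at least 8 values", call. = FALSE)
  d <- sign(outer(x, x, "-"))      # d[i, j] = sign(x_i - x_j)
  u <- vapply(seq_len(n - 1), function(t) {
    sum(d[(t + 1):n, 1:t])
  }, numeric(1))
  k <- max(abs(u))
  tibble(
    n = n,
    changepoint = which.max(abs(u)),
    k_statistic = k,
    p_value = min(1, 2 * exp(-6 * k^2 / (n^3 + n^2)))
  )
}
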