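#' Define a synthetic flux-site scenario
#'
#' Bundles everything the synthetic generators need: the site span and
#' latitude, per-variable seasonal cycles (annual mean, amplitude, phase as
#' the day of year of the seasonal maximum), per-variable linear trends,
#' AR(1) noise, and the coefficients of the daily NEE model
#' \deqn{NEE_d = r_0 q_{10}^{(T_d - 10)/10} - lue \cdot Rg_d \cdot
#'   ramp(T_d) \cdot SWC_d/(SWC_d + swc_{1/2}) + \varepsilon_d}
#' where `ramp` rises linearly 0 to 1 on `[t_low, t_opt]` and falls 1 to 0 on
#' `[t_opt, t_high]`. Negative NEE is net uptake.
#'
#' The defaults emulate a subalpine evergreen conifer site: mean annual air
#' temperature near 4.3 C, annual precipitation near 880 mm, a single
#' contiguous warm season, and a net-uptake period running from late March to
#' mid October.
#'
#' @param n_years Number of simulated years.
#' @param start_year First calendar year.
#' @param latitude Site latitude in decimal degrees.
#' @param seasonal Named list of per-variable seasonal parameter lists, each
#'   `list(mean =, amplitude =, phase =, trend =, sd =, ar1 =)`. Variables:
#'   `t_air_mean`, `t_air_min`, `t_air_max`, `rg`, `rh`, `swc`, `prec`.
#'   Partial overrides are merged over the defaults.
#' @param nee Named list of NEE-model coefficients (`r0`, `q10`, `lue`,
#'   `t_low`, `t_opt`, `t_high`, `swc_half`, `sd`, `ar1`, `trend`); partial
#'   overrides merged over defaults. `trend` is an additive drift of the daily
#'   NEE in g C m^-2 d^-1 per year (negative = strengthening sink).
#' @param seed Integer seed; the same seed and scenario give bit-identical
#'   output.
#' @return An object of class `flux_scenario`.
#' @examples
#' sc <- flux_scenario(n_years = 3, seed = 1)
#' met <- generate_met(sc)
#' @export
flux_scenario <- function(n_years = 26, start_year = 1997, latitude = 46.815,
                          seasonal = list(), nee = list(), seed = 1L) {
  default_seasonal <- list(
    t_air_mean = list(mean = 4.3, amplitude = 7.8, phase = 200, trend = 0, sd = 2.5, ar1 = 0.65),
    t_air_min  = list(mean = -0.7, amplitude = 7.5, phase = 200, trend = 0, sd = 2.8, ar1 = 0.60),
    t_air_max  = list(mean = 9.3, amplitude = 8.5, phase = 200, trend = 0, sd = 2.8, ar1 = 0.60),
    rg         = list(mean = 152, amplitude = 95, phase = 172, trend = 0, sd = 38, ar1 = 0.30),
    rh         = list(mean = 75, amplitude = 4, phase = 20, trend = 0, sd = 8, ar1 = 0.40),
    swc        = list(mean = 25.8, amplitude = 3, phase = 120, trend = 0, sd = 1.2, ar1 = 0.95),
    prec       = list(mean = 2.4, amplitude = 1.0, phase = 200, trend = 0, sd = 4, ar1 = 0.15)
  )
  default_nee <- list(
    r0 = 1.9, q10 = 2.0, lue = 0.024,
    t_low = -5, t_opt = 10, t_high = 35, swc_half = 10,
    sd = 0.8, ar1 = 0.6, trend = 0
  )
  bad <- setdiff(names(seasonal), names(default_seasonal))
  if (length(bad)) stop("unknown seasonal variable(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  for (v in names(seasonal)) {
    bad_f <- setdiff(names(seasonal[[v]]), names(default_seasonal[[v]]))
    if (length(bad_f)) stop("unknown field(s) for ", v, ": ",
                            paste(bad_f, collapse = ", "), call. = FALSE)
    default_seasonal[[v]][names(seasonal[[v]])] <- seasonal[[v]]
  }
  bad_n <- setdiff(names(nee), names(default_nee))
  if (length(bad_n)) stop("unknown NEE coefficient(s): ",
                          paste(bad_n, collapse = ", "), call. = FALSE)
  default_nee[names(nee)] <- nee

  sc <- structure(
    list(
      n_years = as.integer(n_years),
      start_year = as.integer(start_year),
      latitude = latitude,
      seasonal = default_seasonal,
      nee = default_nee,
      seed = as.integer(seed)
    ),
    class = "flux_scenario"
  )
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  if (sc$n_years < 1) stop("invalid scenario: n_years must be >= 1", call. = FALSE)
  if (!is.finite(sc$latitude)) stop("invalid scenario: latitude", call. = FALSE)
  for (v in names(sc$seasonal)) {
    p <- sc$seasonal[[v]]
    if (p$amplitude < 0) stop("invalid scenario: amplitude of ", v,
                              " must be >= 0", call. = FALSE)
    if (p$sd < 0) stop("invalid scenario: sd of ", v, " must be >= 0",
                       call. = FALSE)
    if (p$ar1 < 0 || p$ar1 >= 1) stop("invalid scenario: ar1 of ", v,
                                      " must be in [0, 1)", call. = FALSE)
  }
  n <- sc$nee
  if (!(n$t_low < n$t_opt && n$t_opt < n$t_high)) {
    stop("invalid scenario: need t_low < t_opt < t_high", call. = FALSE)
  }
  if (n$sd < 0) stop("invalid scenario: nee sd must be >= 0", call. = FALSE)
  if (n$ar1 < 0 || n$ar1 >= 1) stop("invalid scenario: nee ar1 must be in [0, 1)",
                                    call. = FALSE)
  invisible(sc)
}

#' Read a scenario from a YAML file
#'
#' The YAML mirrors the arguments of [flux_scenario()]: top-level `n_years`,
#' `start_year`, `latitude`, `seed`, plus optional `seasonal:` and `nee:`
#' blocks with partial overrides.
#'
#' @param path Path to the YAML file.
#' @return A `flux_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  flux_scenario(
    n_years = y$n_years %||% 26,
    start_year = y$start_year %||% 1997,
    latitude = y$latitude %||% 46.815,
    seasonal = y$seasonal %||% list(),
    nee = y$nee %||% list(),
    seed = y$seed %||% 1L
  )
}

#' @export
print.flux_scenario <- function(x, ...) {
  cat("<flux_scenario> ", x$n_years, " years from ", x$start_year,
      ", latitude ", x$latitude, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
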