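test_that("constructed uptake seasons are recovered exactly", {
  # negative block DOY 100..250, window 1 so the smoothed series is the raw one
  nee <- rep(1, 365); nee[100:250] <- -1
  out <- extract_cup(make_daily_year(nee), window = 1)
  expect_equal(out$sos_doy, 100)
  expect_equal(out$eos_doy, 250)
  expect_equal(out$cup_length, 151)
  expect_false(out$no_cup)
  expect_equal(out$n_release_days_within, 0)
  expect_equal(out$n_uptake_days_outside, 0)
})

test_that("an all-positive year has no CUP", {
  out <- extract_cup(make_daily_year(rep(0.5, 365)))
  expect_true(out$no_cup)
  expect_true(is.na(out$sos_doy))
  expect_true(is.na(out$eos_doy))
  expect_true(is.na(out$cup_length))
})

test_that("short negative dips are rejected by the persistence rule", {
  # 7-day dip at DOY 60..66, real season DOY 100..250 (window 1 keeps the
  # dip 7 days long after smoothing)
  nee <- rep(1, 365)
  nee[60:66] <- -1
  nee[100:250] <- -1
  out <- extract_cup(make_daily_year(nee), window = 1, persistence = 14)
  expect_equal(out$sos_doy, 100)
  expect_equal(out$eos_doy, 250)

  # symmetric rejection at the tail
  nee2 <- rep(1, 365)
  nee2[100:250] <- -1
  nee2[300:305] <- -1
  out2 <- extract_cup(make_daily_year(nee2), window = 1, persistence = 14)
  expect_equal(out2$eos_doy, 250)
})

test_that("a smoothed value of exactly zero is non-negative", {
  nee <- rep(1, 365)
  nee[100:250] <- -1
  nee[100] <- 0   # window 1: day 100 is exactly zero
  out <- extract_cup(make_daily_year(nee), window = 1)
  expect_equal(out$sos_doy, 101)
})

test_that("extraction agrees with the exhaustive-search oracle on short series", {
  dates <- as.Date("2018-01-10") + 0:59
  for (seed in 1:200) {
    withr::with_seed(seed, {
      nee <- rnorm(60, mean = 0, sd = 1)
    })
    got <- extract_cup(tibble::tibble(date = dates, nee = nee),
                       window = 3, persistence = 4, min_coverage = 1)
    want <- oracle_cup(nee, window = 3, persistence = 4)
    doy0 <- lubridate::yday(dates[1]) - 1L
    if (is.na(want$sos)) {
      expect_true(got$no_cup)
    } else {
      expect_equal(got$sos_doy, want$sos + doy0)
      expect_equal(got$eos_doy, want$eos + doy0)
      expect_equal(got$cup_length, got$eos_doy - got$sos_doy + 1L)
    }
  }
})

test_that("raising all NEE by a constant never lengthens the CUP", {
  for (seed in 1:30) {
    withr::with_seed(seed, {
      nee <- 0.8 * sin(2 * pi * ((1:365) - 260) / 365) + rnorm(365, sd = 0.3)
    })
    base <- extract_cup(make_daily_year(nee))
    up <- extract_cup(make_daily_year(nee + 0.4))
    if (base$no_cup) {
      # nothing to compare: raising can only keep it undefined
      expect_true(up$no_cup || up$cup_length <= 365)
    } else if (!up$no_cup) {
      expect_gte(up$sos_doy, base$sos_doy)
      expect_lte(up$eos_doy, base$eos_doy)
      expect_lte(up$cup_length, base$cup_length)
    }
  }
})

test_that("extraction is deterministic and errors on sparse years", {
  withr::with_seed(99, {
    nee <- rnorm(365, -0.2, 1)
  })
  d <- make_daily_year(nee)
  expect_identical(extract_cup(d), extract_cup(d))

  sparse <- d
  sparse$nee[1:100] <- NA
  expect_error(extract_cup(sparse), "2018")
})

test_that("release/uptake day counts come from the unsmoothed series", {
  nee <- rep(1, 365)
  nee[100:250] <- -1
  nee[150:152] <- 0.5   # 3 release days inside the season
  nee[20:24] <- -0.5    # 5 uptake days outside
  out <- extract_cup(make_daily_year(nee), window = 1)
  # the inner positive days split the smoothed run; persistence still holds
  expect_equal(out$n_release_days_within, 3)
  expect_equal(out$n_uptake_days_outside, 5)
  expect_equal(out$pct_release_within, 100 * 3 / out$cup_length)
})

test_that("cup_summary reports means, extremes and trends", {
  # noise-free lengthening: SOS fixed at 90, EOS advancing 1 day per year
  years <- 2001:2010
  res <- purrr::map_dfr(seq_along(years), function(i) {
    nee <- rep(1, 365)
    nee[90:(250 + i)] <- -1
    d <- make_daily_year(nee, year = years[i])
    extract_cup(d, window = 1)
  })
  smry <- cup_summary(res)
  expect_equal(smry$mean[smry$metric == "sos_doy"], 90)
  expect_equal(smry$sen_slope[smry$metric == "eos_doy"], 1)
  expect_equal(smry$sen_slope[smry$metric == "cup_length"], 1)
  expect_equal(smry$sd[smry$metric == "sos_doy"], 0)
  expect_equal(smry$max_year[smry$metric == "eos_doy"], 2010)

  # identical years: zero SD, zero slope
  same <- purrr::map_dfr(years, function(y) {
    nee <- rep(1, 365); nee[90:260] <- -1
    extract_cup(make_daily_year(nee, year = y), window = 1)
  })
  s2 <- cup_summary(same)
  expect_true(all(s2$sd == 0))
  expect_true(all(s2$sen_slope == 0))
})

test_that("mean length equals mean(EOS) - mean(SOS) + 1 over defined years", {
  withr::with_seed(4, {
    sc <- flux_scenario(n_years = 8, start_year = 2001, seed = 4)
  })
  daily <- generate_daily_nee(sc, generate_met(sc))
  res <- extract_cup_all(daily)
  defined <- dplyr::filter(res, !no_cup)
  expect_equal(mean(defined$cup_length),
               mean(defined$eos_doy) - mean(defined$sos_doy) + 1)
})

test_that("phenology-NEE regressions recover exact linear relations and ranks", {
  years <- 2001:2010
  res <- purrr::map_dfr(seq_along(years), function(i) {
    nee <- rep(1, 365)
    nee[90:(240 + 3 * i)] <- -1
    extract_cup(make_daily_year(nee, year = years[i]), window = 1)
  })
  # annual NEE exactly linear in CUP length
  ann <- tibble::tibble(year = years, nee_annual = -2 * res$cup_length + 100)
  rel <- suppressWarnings(phenology_nee_relationships(ann, res))  # exact fit
  row <- rel[rel$metric == "cup_length", ]
  expect_equal(row$r_squared, 1)
  expect_equal(row$slope, -2)
  expect_equal(row$spearman_rho, -1)

  # rank oracle on a scrambled, monotone-free pairing
  withr::with_seed(6, {
    ann2 <- tibble::tibble(year = years, nee_annual = rnorm(10))
  })
  rel2 <- phenology_nee_relationships(ann2, res)
  x <- res$cup_length
  y <- ann2$nee_annual
  rho_oracle <- 1 - 6 * sum((rank(x) - rank(y))^2) / (10 * (10^2 - 1))
  expect_equal(rel2$spearman_rho[rel2$metric == "cup_length"], rho_oracle,
               tolerance = 1e-12)

  # degenerate variance is flagged
  same <- purrr::map_dfr(years, function(y) {
    nee <- rep(1, 365); nee[90:260] <- -1
    extract_cup(make_daily_year(nee, year = y), window = 1)
  })
  rel3 <- phenology_nee_relationships(ann2, same)
  expect_true(all(rel3$degenerate))
})
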