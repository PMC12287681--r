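# build an attribution object directly from known SHAP columns, so the
# attribution statistics can be tested against constructed ground truth
make_attribution <- function(dates, shap, base_value = 0) {
  out <- tibble::tibble(
    date = dates,
    prediction = base_value + rowSums(shap)
  )
  out <- dplyr::bind_cols(out, shap)
  structure(
    out,
    base_value = base_value,
    feature_names = names(shap),
    metrics = tibble::tibble(r_squared = NA_real_, rmse = NA_real_,
                             n_train = 0L, n_test = 0L),
    seed = 0L,
    class = c("nee_attribution", class(out))
  )
}

fast_params <- list(subsample = 1, colsample_bytree = 1, eta = 0.3,
                    max_depth = 4)

test_that("a noise-free linear target is fit almost perfectly, a shuffled one is not", {
  sc <- small_scenario(n_years = 6)
  met <- generate_met(sc)
  fm <- build_features(met, default_feature_specs()[c(1, 8, 16), ])
  fm$nee <- 0.01 * fm$rg - 1

  expect_warning(
    m <- train_gbm(fm[1:900, ], nrounds = 200, params = fast_params, seed = 1),
    "rows"
  )
  expect_gte(glance(m)$r_squared, 0.99)

  withr::with_seed(2, {
    fm_null <- fm
    fm_null$nee <- sample(fm_null$nee)
  })
  m0 <- suppressWarnings(
    train_gbm(fm_null[1:900, ], nrounds = 100, params = fast_params, seed = 1)
  )
  expect_lte(glance(m0)$r_squared, 0.1)
})

test_that("train/test split is seeded, day-level and at the requested fraction", {
  sc <- small_scenario(n_years = 4)
  fm <- build_features(generate_met(sc), default_feature_specs()[c(1, 8), ])
  withr::with_seed(50, fm$nee <- rnorm(nrow(fm)))
  m1 <- suppressWarnings(train_gbm(fm, nrounds = 5, seed = 7))
  m2 <- suppressWarnings(train_gbm(fm, nrounds = 5, seed = 7))
  m3 <- suppressWarnings(train_gbm(fm, nrounds = 5, seed = 8))
  expect_identical(m1$train_dates, m2$train_dates)
  expect_false(identical(m1$train_dates, m3$train_dates))
  expect_equal(length(m1$train_dates) / nrow(fm), 0.75, tolerance = 0.001)
  expect_length(intersect(m1$train_dates, m1$test_dates), 0)
})

test_that("depth-1 tree attributions equal hand-computed leaf deviations", {
  n <- 400
  withr::with_seed(12, {
    x_bin <- sample(c(0, 1), n, replace = TRUE)
  })
  fm <- tibble::tibble(
    date = as.Date("2001-01-01") + seq_len(n) - 1,
    xsplit = x_bin,
    nee = ifelse(x_bin == 1, 2, -1)
  )
  m <- suppressWarnings(train_gbm(
    fm,
    nrounds = 1,
    params = list(max_depth = 1, eta = 1, lambda = 0, subsample = 1,
                  colsample_bytree = 1, base_score = 0),
    seed = 3
  ))
  attr_out <- compute_attributions(m, fm)

  # leaf values are the train-split residual means; the SHAP baseline is the
  # cover-weighted mean of the leaf values, so each day's attribution is its
  # leaf value minus that mean
  train <- fm[fm$date %in% m$train_dates, ]
  leaf0 <- mean(train$nee[train$xsplit == 0])
  leaf1 <- mean(train$nee[train$xsplit == 1])
  w0 <- sum(train$xsplit == 0)
  w1 <- sum(train$xsplit == 1)
  baseline <- (w0 * leaf0 + w1 * leaf1) / (w0 + w1)

  expect_equal(attr(attr_out, "base_value"), baseline, tolerance = 1e-6)
  expect_equal(attr_out$xsplit[fm$xsplit == 0][1], leaf0 - baseline,
               tolerance = 1e-6)
  expect_equal(attr_out$xsplit[fm$xsplit == 1][1], leaf1 - baseline,
               tolerance = 1e-6)
})

test_that("attributions are additive and vanish for a constant model", {
  sc <- small_scenario(n_years = 5)
  met <- generate_met(sc)
  daily <- generate_daily_nee(sc, met)
  fm <- build_features(met, default_feature_specs()[c(1, 8, 13, 16), ], daily)
  m <- suppressWarnings(train_gbm(fm, nrounds = 60, params = fast_params,
                                  seed = 2))
  a <- compute_attributions(m, fm)
  feats <- attr(a, "feature_names")
  resid <- abs(rowSums(as.matrix(tibble::as_tibble(a)[feats])) +
                 attr(a, "base_value") - a$prediction)
  # BIAS is constant across rows for path-dependent TreeSHAP
  expect_lt(max(resid / pmax(abs(a$prediction), 1)), 1e-5)

  flat <- fm
  flat$nee <- 1.5
  m0 <- suppressWarnings(train_gbm(flat, nrounds = 10, seed = 2))
  a0 <- compute_attributions(m0, flat)
  expect_equal(max(abs(as.matrix(tibble::as_tibble(a0)[feats]))), 0,
               tolerance = 1e-7)

  expect_error(compute_attributions(m, fm[, c("date", "t_air_mean", "nee")]),
               "schema")
})

test_that("driver-shift statistic recovers constructed steps exactly", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  doy <- lubridate::yday(dates)
  sos <- 100; eos <- 280
  shap <- tibble::tibble(
    step_feat = ifelse(doy >= sos, -0.5, 0.5),   # -1 step exactly at SOS
    flat_feat = 0.25,
    ramp_feat = ifelse(doy >= eos, 0.8, 0.1)     # +0.7 step at EOS
  )
  a <- make_attribution(dates, shap)
  pheno <- tibble::tibble(
    year = 2001:2003, sos_doy = sos, eos_doy = eos,
    cup_length = eos - sos + 1, no_cup = FALSE
  )
  out <- sos_eos_driver_shift(a, pheno)
  get <- function(tr, f) out$median_shift[out$transition == tr & out$feature == f]
  expect_equal(get("sos", "step_feat"), -1)
  expect_equal(get("sos", "flat_feat"), 0)
  expect_equal(get("eos", "ramp_feat"), 0.7)
  expect_equal(get("eos", "flat_feat"), 0)
  expect_true(all(out$n_years == 3))

  # an asymmetric hand-built window: medians computed by hand
  y1 <- dates >= as.Date("2001-01-01") & dates <= as.Date("2001-12-31")
  vals <- shap
  vals$step_feat[y1][sos + (-10:-1)] <- c(1, 1, 1, 2, 2, 3, 3, 3, 4, 9)
  vals$step_feat[y1][sos + (1:10)] <- c(0, 0, 1, 1, 1, 1, 2, 2, 5, 5)
  a2 <- make_attribution(dates, vals)
  out2 <- sos_eos_driver_shift(a2, pheno[1, ])
  expect_equal(out2$median_shift[out2$transition == "sos" &
                                   out2$feature == "step_feat"],
               median(c(0, 0, 1, 1, 1, 1, 2, 2, 5, 5)) -
                 median(c(1, 1, 1, 2, 2, 3, 3, 3, 4, 9)))

  # a year whose window is incomplete is skipped with a warning
  pheno_bad <- dplyr::bind_rows(
    pheno,
    tibble::tibble(year = 2004, sos_doy = 5, eos_doy = 300,
                   cup_length = 296, no_cup = FALSE)
  )
  w <- testthat::capture_warnings(out3 <- sos_eos_driver_shift(a, pheno_bad))
  expect_true(all(grepl("2004", w)))
  expect_gte(length(w), 1)
  expect_true(all(out3$n_years == 3))
})

test_that("mean daily attribution averages years and honors availability windows", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  doy <- lubridate::yday(dates)
  yr <- lubridate::year(dates)
  shap <- tibble::tibble(
    f1 = cos(2 * pi * doy / 365),
    f2 = ifelse(yr == 2001, 1, 3)
  )
  a <- make_attribution(dates, shap)
  md <- mean_daily_attribution(a)
  expect_equal(nrow(md), 365 * 2)
  # identical years: the mean equals either year
  expect_equal(md$mean_shap[md$feature == "f1"],
               cos(2 * pi * (1:365) / 365))
  expect_equal(unique(md$mean_shap[md$feature == "f2"]), 2)

  # availability from 2002 changes only the restricted feature
  md2 <- mean_daily_attribution(a, availability = list(f2 = 2002))
  expect_equal(unique(md2$mean_shap[md2$feature == "f2"]), 3)
  expect_equal(md2$mean_shap[md2$feature == "f1"],
               md$mean_shap[md$feature == "f1"])
})

test_that("favorable ranges bracket the constructed negative-SHAP interval", {
  n <- 3000
  withr::with_seed(9, {
    x <- runif(n, -10, 10)
  })
  dates <- as.Date("2001-01-01") + seq_len(n) - 1
  a_root <- -2.5; b_root <- 4.5
  shap <- tibble::tibble(f = (x - a_root) * (x - b_root))
  a <- make_attribution(dates, shap)
  features <- tibble::tibble(date = dates, f = x)

  out <- favorable_ranges(a, features, "f", n_bins = 50)
  expect_equal(nrow(out), 1)
  bin_width <- 20 / 50 * 2.5   # equal-count bins on uniform data, generous
  expect_lt(abs(out$lower - a_root), bin_width)
  expect_lt(abs(out$upper - b_root), bin_width)

  # all-negative SHAP: the full observed range
  a_neg <- make_attribution(dates, tibble::tibble(f = -1 - 0 * x))
  out_neg <- favorable_ranges(a_neg, features, "f")
  expect_equal(nrow(out_neg), 1)
  expect_equal(out_neg$lower, min(x))
  expect_equal(out_neg$upper, max(x))

  # all-positive SHAP: no intervals
  a_pos <- make_attribution(dates, tibble::tibble(f = 1 + 0 * x))
  expect_equal(nrow(favorable_ranges(a_pos, features, "f")), 0)
})

test_that("seasonal attribution trends flag only the drifting feature", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2014-12-31"), by = "day")
  yr <- lubridate::year(dates)
  mon <- lubridate::month(dates)
  withr::with_seed(33, {
    shap <- tibble::tibble(
      drifting = ifelse(mon %in% 6:8, 0.01 * (yr - 2001), 0) +
        rnorm(length(dates), 0, 0.002),
      stable = rnorm(length(dates), 0, 0.002)
    )
  })
  a <- make_attribution(dates, shap)
  out <- seasonal_attribution_trends(a, season = "JJA")
  drift_row <- out[out$feature == "drifting", ]
  expect_true(drift_row$significant)
  expect_gt(drift_row$sen_slope, 0)
  expect_equal(drift_row$sen_slope, 0.01, tolerance = 0.002)
  expect_false(out$significant[out$feature == "stable"])
})

test_that("true drivers out-rank noise decoys in summed |SHAP| importance", {
  for (seed in 1:3) {
    sc <- small_scenario(n_years = 6, seed = seed)
    met <- generate_met(sc)
    daily <- generate_daily_nee(sc, met)
    fm <- build_features(
      met,
      tibble::tribble(
        ~name,         ~base_variable, ~transform, ~window, ~lag,
        "rg",          "rg",           "none",     1L,      0L,
        "t_air_mean",  "t_air_mean",   "none",     1L,      0L,
        "swc",         "swc",          "none",     1L,      0L,
        "daylength",   "daylength",    "none",     1L,      0L
      ),
      daily
    )
    withr::with_seed(1000 + seed, {
      fm$decoy1 <- rnorm(nrow(fm))
      fm$decoy2 <- rnorm(nrow(fm))
    })
    m <- suppressWarnings(train_gbm(fm, nrounds = 80, params = fast_params,
                                    seed = seed))
    a <- compute_attributions(m, fm)
    imp <- tidy(a) |>
      dplyr::group_by(feature) |>
      dplyr::summarise(total = sum(abs(shap)), .groups = "drop")
    rank_of <- function(f) rank(-imp$total)[imp$feature == f]
    expect_lt(rank_of("rg"), rank_of("decoy1"))
    expect_lt(rank_of("rg"), rank_of("decoy2"))
    expect_lt(rank_of("t_air_mean"), rank_of("decoy1"))
    expect_lt(rank_of("t_air_mean"), rank_of("decoy2"))
  }
})

test_that("tidiers expose long attributions, importance and fit metrics", {
  sc <- small_scenario(n_years = 4)
  met <- generate_met(sc)
  daily <- generate_daily_nee(sc, met)
  fm <- build_features(met, default_feature_specs()[c(1, 8, 16), ], daily)
  m <- suppressWarnings(train_gbm(fm, nrounds = 40, params = fast_params,
                                  seed = 5))
  a <- compute_attributions(m, fm)

  long <- tidy(a)
  expect_setequal(names(long), c("date", "feature", "shap"))
  expect_equal(nrow(long), nrow(a) * 3)

  g <- glance(a)
  expect_true(all(c("r_squared", "rmse", "base_value", "n_days") %in% names(g)))

  imp <- tidy(m)
  expect_true(all(imp$gain >= 0))
  expect_equal(sum(imp$gain), 1, tolerance = 1e-6)
})
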