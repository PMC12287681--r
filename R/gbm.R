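#' Fit a gradient-boosted tree model of daily NEE
#'
#' Trains an xgboost regression on the feature matrix with a random day-level
#' train/test split (default 75/25, seeded). Missing predictor values are
#' routed natively by the trees (default-direction learning), so predictors
#' with partial availability need no imputation. Held-out performance is
#' reported as R^2 and RMSE in target units (g C m^-2 d^-1).
#'
#' The default hyperparameters are `max_depth = 6`, `eta = 0.05`,
#' `subsample = 0.8`, `colsample_bytree = 0.8`; when `nrounds = NULL` the
#' number of boosting rounds is chosen by 10-fold cross-validated early
#' stopping on the training split (up to `max_rounds`, patience 20).
#'
#' @param features Feature matrix from [build_features()] including the `nee`
#'   target column.
#' @param split_fraction Fraction of days used for training (default 0.75).
#' @param params Named list merged over the default xgboost parameters.
#' @param nrounds Number of boosting rounds, or `NULL` for CV early stopping.
#' @param max_rounds Upper bound for CV-selected rounds (default 400).
#' @param nfold Folds for the CV round selection (default 10).
#' @param seed Integer seed controlling the split, subsampling and CV folds.
#' @return An object of class `nee_gbm`: the booster, feature names, train /
#'   test dates, metrics, chosen rounds, parameters and seed. Use [glance()]
#'   for the fit metrics and [tidy()] for feature importance.
#' @export
train_gbm <- function(features, split_fraction = 0.75, params = list(),
                      nrounds = NULL, max_rounds = 400, nfold = 10,
                      seed = 1L) {
  stopifnot(is.data.frame(features), "nee" %in% names(features),
            "date" %in% names(features))
  features <- dplyr::filter(features, is.finite(.data$nee))
  n <- nrow(features)
  if (n < 1000) {
    warning("only ", n, " rows; fit metrics may be unstable", call. = FALSE)
  }
  feat_names <- setdiff(names(features), c("date", "nee"))
  x <- as.matrix(features[feat_names])
  y <- features$nee

  default_params <- list(
    objective = "reg:squarederror",
    max_depth = 6,
    eta = 0.05,
    subsample = 0.8,
    colsample_bytree = 0.8,
    nthread = 1
  )
  default_params[names(params)] <- params

  fit <- withr::with_seed(seed, {
    train_idx <- sort(sample.int(n, size = round(split_fraction * n)))
    test_idx <- setdiff(seq_len(n), train_idx)
    dtrain <- xgboost::xgb.DMatrix(x[train_idx, , drop = FALSE],
                                   label = y[train_idx], missing = NA)
    if (is.null(nrounds)) {
      cv <- xgboost::xgb.cv(
        params = default_params, data = dtrain, nrounds = max_rounds,
        nfold = nfold, early_stopping_rounds = 20, verbose = 0
      )
      nrounds <- cv$early_stop$best_iteration %||% cv$best_iteration
    }
    booster <- xgboost::xgb.train(
      params = default_params, data = dtrain, nrounds = nrounds, verbose = 0
    )
    list(booster = booster, train_idx = train_idx, test_idx = test_idx,
         nrounds = nrounds)
  })

  dtest <- xgboost::xgb.DMatrix(x[fit$test_idx, , drop = FALSE], missing = NA)
  pred <- predict(fit$booster, dtest)
  obs <- y[fit$test_idx]
  rmse <- sqrt(mean((pred - obs)^2))
  r2 <- 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)

  structure(
    list(
      booster = fit$booster,
      feature_names = feat_names,
      train_dates = features$date[fit$train_idx],
      test_dates = features$date[fit$test_idx],
      nrounds = fit$nrounds,
      params = default_params,
      split_fraction = split_fraction,
      seed = seed,
      metrics = tibble(r_squared = r2, rmse = rmse,
                       n_train = length(fit$train_idx),
                       n_test = length(fit$test_idx))
    ),
    class = "nee_gbm"
  )
}

#' @export
print.nee_gbm <- function(x, ...) {
  cat("<nee_gbm> ", length(x$feature_names), " features, ",
      x$nrounds, " rounds; held-out R2 = ", round(x$metrics$r_squared, 3),
      ", RMSE = ", round(x$metrics$rmse, 3), " g C m-2 d-1\n", sep = "")
  invisible(x)
}

#' @rdname train_gbm
#' @param x,model A fitted `nee_gbm`.
#' @param ... Unused.
#' @export
glance.nee_gbm <- function(x, ...) {
  dplyr::mutate(x$metrics, nrounds = x$nrounds, seed = x$seed)
}

#' @rdname train_gbm
#' @export
tidy.nee_gbm <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  tibble(
    feature = imp$Feature,
    gain = imp$Gain,
    cover = imp$Cover,
    frequency = imp$Frequency
  )
}

#' Exact per-day, per-feature SHAP attributions for a fitted NEE model
#'
#' Uses the tree-path-dependent TreeSHAP algorithm built into xgboost
#' (`predcontrib = TRUE`), which is exactly additive for tree ensembles: for
#' every day `base_value + sum(SHAP) = prediction`. The reported prediction
#' is that additive decomposition; it is verified against the booster's own
#' (single-precision) predictions and an error is raised if they disagree
#' beyond float32 rounding. Attributions are in target units (g C m^-2 d^-1)
#' and are computed for all supplied days (train and test alike).
#'
#' @param model A fitted [train_gbm()] object.
#' @param features Feature matrix with the same schema the model was trained
#'   on (`date` + feature columns; a `nee` column is carried through if
#'   present).
#' @return An object of class `nee_attribution`: a tibble with `date`,
#'   `prediction`, optionally `nee`, and one SHAP column per feature, plus
#'   attributes `base_value`, `feature_names`, `metrics`, `seed`. [tidy()]
#'   pivots it to long form.
#' @export
compute_attributions <- function(model, features) {
  stopifnot(inherits(model, "nee_gbm"))
  missing_feat <- setdiff(model$feature_names, names(features))
  if (length(missing_feat)) {
    stop("feature schema mismatch; missing: ",
         paste(missing_feat, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(features[model$feature_names])
  dmat <- xgboost::xgb.DMatrix(x, missing = NA)
  contrib <- predict(model$booster, dmat, predcontrib = TRUE)
  colnames(contrib) <- c(model$feature_names, "BIAS")

  # TreeSHAP is exactly additive, so the reported prediction is the additive
  # decomposition itself; the booster's own single-precision predictions must
  # agree with it to within float32 rounding
  pred <- rowSums(contrib)
  pred_f32 <- predict(model$booster, dmat)
  denom <- pmax(abs(pred_f32), 1)
  if (any(abs(pred - pred_f32) / denom > 1e-4)) {
    stop("SHAP additivity violated beyond single-precision rounding",
         call. = FALSE)
  }

  out <- tibble(date = features$date, prediction = pred)
  if ("nee" %in% names(features)) out$nee <- features$nee
  out <- dplyr::bind_cols(
    out,
    as_tibble(contrib[, model$feature_names, drop = FALSE])
  )
  structure(
    out,
    base_value = mean(contrib[, "BIAS"]),
    feature_names = model$feature_names,
    metrics = model$metrics,
    seed = model$seed,
    class = c("nee_attribution", class(out))
  )
}

#' @rdname compute_attributions
#' @param x An `nee_attribution`.
#' @param ... Unused.
#' @export
tidy.nee_attribution <- function(x, ...) {
  feats <- attr(x, "feature_names")
  as_tibble(x) %>%
    dplyr::select("date", dplyr::all_of(feats)) %>%
    tidyr::pivot_longer(-"date", names_to = "feature", values_to = "shap")
}

#' @rdname compute_attributions
#' @export
glance.nee_attribution <- function(x, ...) {
  dplyr::mutate(attr(x, "metrics"),
                base_value = attr(x, "base_value"),
                n_days = nrow(x))
}
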