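# Behavior prediction from hub-region activity and TH measures.
#
# Five regressors are fitted on one seeded 0.75:0.25 train/test split with
# 5-fold cross-validation inside the training portion: a Gaussian linear
# model on standardized features (GLM), extra trees (ET), random forest (RF),
# classic gradient boosting (GBM) and extreme gradient boosting (XGB).
# Held-out R^2 is the accuracy metric and held-out RMSE the overfitting
# guard. Feature importances are |standardized coefficient| for the GLM and
# impurity/gain importances for the ensembles, reported raw plus on two
# normalised scales: proportions (L1, sums to 1) and relative (max = 1).

ML_MODELS <- c("GLM", "ET", "RF", "GBM", "XGB")

#' Default feature set: hub-region activity plus TH measures
#'
#' The eight hub regions identified by the network stage (M1, DG, Cg1, CA3,
#' VL, PHA, VTA, LC) together with nigral TH cell counts (`th_sn`) and
#' striatal TH optical density (`th_st`).
#'
#' @export
DEFAULT_ML_FEATURES <- c("M1", "DG", "Cg1", "CA3", "VL", "PHA", "VTA", "LC",
                         "th_sn", "th_st")

#' Dual normalisation of feature importances
#'
#' @param raw named non-negative numeric vector with at least one positive
#'   entry.
#' @return list with `proportion` (`raw / sum(raw)`, sums to 1) and
#'   `relative` (`raw / max(raw)`, maximum 1) — the two scales importance
#'   tables are conventionally reported on.
#' @export
normalize_importance <- function(raw) {
  stopifnot(is.numeric(raw), all(raw >= 0))
  if (sum(raw) == 0) stop("all importances are zero; nothing to normalize")
  list(proportion = raw / sum(raw), relative = raw / max(raw))
}

#' L1-normalise per-model RMSE values
#'
#' @param rmse_by_model named non-negative numeric vector, at least one
#'   positive.
#' @return The vector divided by its sum (so it sums to 1).
#' @export
normalize_rmse <- function(rmse_by_model) {
  stopifnot(is.numeric(rmse_by_model), all(rmse_by_model >= 0))
  if (sum(rmse_by_model) == 0) stop("all RMSE values are zero; nothing to normalize")
  rmse_by_model / sum(rmse_by_model)
}

r_squared <- function(obs, pred) {
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

rmse <- function(obs, pred) sqrt(mean((obs - pred)^2))

fit_one_model <- function(model, x_train, y_train, x_test, seed) {
  set.seed(seed)
  switch(model,
    GLM = {
      mu <- colMeans(x_train); sdv <- apply(x_train, 2, stats::sd)
      sdv[sdv == 0] <- 1
      zs <- function(x) sweep(sweep(x, 2, mu), 2, sdv, `/`)
      df <- data.frame(y = y_train, zs(x_train), check.names = FALSE)
      fit <- stats::lm(y ~ ., data = df)
      coefs <- stats::coef(fit)[-1]
      coefs[is.na(coefs)] <- 0
      list(predict = function(x) unname(stats::predict(
             fit, newdata = data.frame(zs(x), check.names = FALSE))),
           importance = abs(coefs))
    },
    ET = {
      fit <- ranger::ranger(
        x = x_train, y = y_train, num.trees = 500,
        splitrule = "extratrees", num.random.splits = 1,
        replace = FALSE, sample.fraction = 1, mtry = ncol(x_train),
        importance = "impurity", seed = seed)
      list(predict = function(x) stats::predict(fit, data = x)$predictions,
           importance = fit$variable.importance)
    },
    RF = {
      fit <- randomForest::randomForest(x = x_train, y = y_train,
                                        ntree = 500, importance = FALSE)
      imp <- randomForest::importance(fit)[, "IncNodePurity"]
      list(predict = function(x) unname(stats::predict(fit, newdata = x)),
           importance = imp)
    },
    GBM = {
      # classic gradient boosting: shallow trees, shrinkage, no
      # regularisation terms, exact greedy splits
      fit <- xgboost::xgb.train(
        params = list(eta = 0.05, max_depth = 3, subsample = 1,
                      colsample_bytree = 1, lambda = 0, alpha = 0,
                      tree_method = "exact", nthread = 1),
        data = xgboost::xgb.DMatrix(x_train, label = y_train),
        nrounds = 300, verbose = 0)
      list(predict = function(x) stats::predict(fit, xgboost::xgb.DMatrix(x)),
           importance = xgb_gain(fit, colnames(x_train)))
    },
    XGB = {
      fit <- xgboost::xgb.train(
        params = list(eta = 0.1, max_depth = 6, subsample = 0.8,
                      colsample_bytree = 0.8, lambda = 1, nthread = 1),
        data = xgboost::xgb.DMatrix(x_train, label = y_train),
        nrounds = 200, verbose = 0)
      list(predict = function(x) stats::predict(fit, xgboost::xgb.DMatrix(x)),
           importance = xgb_gain(fit, colnames(x_train)))
    },
    stop("unknown model '", model, "'"))
}

xgb_gain <- function(fit, features) {
  imp <- xgboost::xgb.importance(model = fit)
  out <- stats::setNames(numeric(length(features)), features)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  out
}

#' Fit the five behavior-prediction regressors
#'
#' One seeded held-out split at `split` (default 0.75 train), 5-fold CV
#' within the training portion, and a ModelReport per algorithm: held-out
#' R^2 and RMSE, per-fold CV R^2, and raw plus L1- and max-normalised
#' importances.
#'
#' @param cohort cohort data.frame containing the features and target.
#' @param features feature column names (default [DEFAULT_ML_FEATURES]).
#' @param target target column (default `"rotarod_s"`).
#' @param split training fraction of the held-out split (default 0.75).
#' @param cv_folds folds within the training set (default 5).
#' @param seed integer seed governing split, folds and model fitting.
#' @param models subset of `c("GLM","ET","RF","GBM","XGB")` to fit.
#' @param cv_on_full run CV on the full dataset instead of the training
#'   portion (off by default).
#' @return A `model_report`: list with `metrics` (data.frame: model, r2,
#'   rmse, rmse_l1, cv_mean), `cv_scores` (model x fold matrix),
#'   `importance` (long data.frame: model, feature, raw, proportion,
#'   relative), and bookkeeping (`target`, `features`, `seed`, `n_train`,
#'   `n_test`).
#' @export
fit_predictors <- function(cohort, features = DEFAULT_ML_FEATURES,
                           target = "rotarod_s", split = 0.75, cv_folds = 5,
                           seed = 1, models = ML_MODELS, cv_on_full = FALSE) {
  stopifnot(length(features) >= 2, !target %in% features,
            split > 0, split < 1, cv_folds >= 2)
  models <- match.arg(models, ML_MODELS, several.ok = TRUE)
  missing <- setdiff(c(features, target), names(cohort))
  if (length(missing))
    stop("column(s) not in cohort: ", paste(missing, collapse = ", "))
  data <- cohort[stats::complete.cases(cohort[c(features, target)]),
                 c(features, target)]
  n <- nrow(data)
  if (n < cv_folds * 2)
    stop("need at least ", cv_folds * 2, " complete rows; got ", n)
  y_all <- data[[target]]
  if (stats::sd(y_all) == 0) stop("target '", target, "' is constant")
  X_all <- as.matrix(data[features])

  set.seed(seed)
  train_idx <- sort(sample.int(n, round(split * n)))
  test_idx <- setdiff(seq_len(n), train_idx)
  x_train <- X_all[train_idx, , drop = FALSE]; y_train <- y_all[train_idx]
  x_test <- X_all[test_idx, , drop = FALSE];  y_test <- y_all[test_idx]

  cv_x <- if (cv_on_full) X_all else x_train
  cv_y <- if (cv_on_full) y_all else y_train
  set.seed(seed + 1)
  fold_id <- sample(rep(seq_len(cv_folds), length.out = length(cv_y)))

  cv_scores <- matrix(NA_real_, length(models), cv_folds,
                      dimnames = list(models, paste0("fold", seq_len(cv_folds))))
  metrics <- data.frame(model = models, r2 = NA_real_, rmse = NA_real_,
                        cv_mean = NA_real_, stringsAsFactors = FALSE)
  imp_rows <- list()
  for (m in models) {
    fit <- fit_one_model(m, x_train, y_train, x_test, seed)
    pred <- fit$predict(x_test)
    metrics[metrics$model == m, "r2"] <- r_squared(y_test, pred)
    metrics[metrics$model == m, "rmse"] <- rmse(y_test, pred)
    for (f in seq_len(cv_folds)) {
      hold <- fold_id == f
      fit_f <- fit_one_model(m, cv_x[!hold, , drop = FALSE], cv_y[!hold],
                             cv_x[hold, , drop = FALSE], seed + f)
      cv_scores[m, f] <- r_squared(cv_y[hold],
                                   fit_f$predict(cv_x[hold, , drop = FALSE]))
    }
    metrics[metrics$model == m, "cv_mean"] <- mean(cv_scores[m, ])
    raw <- fit$importance[features]
    raw[is.na(raw) | raw < 0] <- 0
    norm <- if (sum(raw) > 0) normalize_importance(raw) else
      list(proportion = raw, relative = raw)
    imp_rows[[m]] <- data.frame(model = m, feature = features,
                                raw = unname(raw),
                                proportion = unname(norm$proportion),
                                relative = unname(norm$relative),
                                stringsAsFactors = FALSE)
  }
  metrics$rmse_l1 <- normalize_rmse(stats::setNames(metrics$rmse, metrics$model))
  structure(list(metrics = metrics[c("model", "r2", "rmse", "rmse_l1", "cv_mean")],
                 cv_scores = cv_scores,
                 importance = do.call(rbind, c(imp_rows, make.row.names = FALSE)),
                 target = target, features = features, seed = seed,
                 n_train = length(train_idx), n_test = length(test_idx)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> target=", x$target, " (train ", x$n_train, ", test ",
      x$n_test, ")\n", sep = "")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Rank fitted models by accuracy, then parsimony
#'
#' Orders models by descending held-out R^2, breaking ties by ascending
#' RMSE — so of two equally accurate models the one with the smaller error
#' (lower overfitting risk) comes first.
#'
#' @param report a `model_report` from [fit_predictors()], or a data.frame
#'   with columns `model`, `r2`, `rmse`.
#' @return The metrics data.frame in rank order, with a `rank` column and a
#'   `"rule"` attribute stating the ordering rule.
#' @export
rank_models <- function(report) {
  metrics <- if (inherits(report, "model_report")) report$metrics else report
  stopifnot(nrow(metrics) >= 1,
            all(c("model", "r2", "rmse") %in% names(metrics)))
  ord <- order(-metrics$r2, metrics$rmse)
  out <- metrics[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "rule") <- "descending r2, ties broken by ascending rmse"
  out
}
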