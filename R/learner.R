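# Minimal learner contract (fit / predict / importance) bound to gradient-
# boosted trees via xgboost. The selection and conformal code only touches
# these functions, so another regressor could be slotted in behind them.

#' Boosted-tree learner specification
#'
#' Hyperparameters of the gradient-boosted tree regressor plus, after tuning,
#' the saved cross-validation fold assignment that downstream conformal
#' calculations reuse.
#'
#' @param max_depth maximum tree depth.
#' @param eta learning rate in (0, 1].
#' @param nrounds number of boosting rounds.
#' @param folds optional integer vector of per-sample fold labels (the saved
#'   CV assignment from tuning).
#' @param seed integer master seed used for fold shuffling downstream.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(max_depth = 3L, eta = 0.3, nrounds = 100L,
                         folds = NULL, seed = 1L) {
  if (!is_count(max_depth)) stopf("max_depth must be a positive integer")
  if (!is.numeric(eta) || eta <= 0 || eta > 1) stopf("eta must lie in (0, 1]")
  if (!is_count(nrounds)) stopf("nrounds must be a positive integer")
  structure(
    list(max_depth = as.integer(max_depth), eta = eta,
         nrounds = as.integer(nrounds), folds = folds, seed = as.integer(seed)),
    class = "learner_spec"
  )
}

xgb_params <- function(spec) {
  xgboost::xgb.params(
    max_depth = spec$max_depth,
    eta = spec$eta,
    objective = "reg:squarederror",
    nthread = 1
  )
}

#' Fit the boosted-tree learner
#'
#' @param spec a [learner_spec()].
#' @param X numeric matrix with named columns.
#' @param y numeric response.
#' @return A fitted booster usable with [predict_learner()] and
#'   [importance_ranking()].
#' @export
fit_learner <- function(spec, X, y) {
  stopifnot(inherits(spec, "learner_spec"))
  if (any(!is.finite(y))) stopf("response contains non-finite values")
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  model <- xgboost::xgb.train(params = xgb_params(spec), data = dm,
                              nrounds = spec$nrounds, verbose = 0)
  attr(model, "feature_names") <- colnames(X)
  model
}

#' Predict from a fitted learner
#'
#' @param model a [fit_learner()] result.
#' @param X numeric matrix with the training columns.
#' @return Numeric vector of predictions.
#' @export
predict_learner <- function(model, X) {
  stats::predict(model, xgboost::xgb.DMatrix(as.matrix(X), nthread = 1))
}

#' Importance ranking of descriptors
#'
#' Descriptors with nonzero total-gain importance, in decreasing order; ties
#' break by original column order, and zero-importance descriptors are
#' appended in original order.
#'
#' @param model a fitted learner from [fit_learner()].
#' @return data.frame with columns `name` and `gain` (zero for unused
#'   descriptors), one row per descriptor, importance-descending.
#' @export
importance_ranking <- function(model) {
  feature_names <- attr(model, "feature_names")
  if (is.null(feature_names)) stopf("model was not fitted through fit_learner()")
  # total gain summed over all splits, normalized to 1 (computed from the
  # tree table; robust for models with very few features)
  tree <- xgboost::xgb.model.dt.tree(model = model)
  splits <- tree[tree$Feature != "Leaf", c("Feature", "Gain")]
  gains <- stats::setNames(rep(0, length(feature_names)), feature_names)
  if (nrow(splits)) {
    agg <- tapply(splits$Gain, splits$Feature, sum)
    gains[names(agg)] <- agg
    if (sum(gains) > 0) gains <- gains / sum(gains)
  }
  ord <- order(-gains, seq_along(gains))
  data.frame(name = feature_names[ord], gain = unname(gains[ord]),
             stringsAsFactors = FALSE)
}

# k-fold CV under a fixed fold assignment; returns out-of-fold predictions
# and (optionally) the per-fold models.
cv_once <- function(spec, X, y, folds, keep_models = FALSE) {
  X <- as.matrix(X)
  preds <- numeric(length(y))
  models <- if (keep_models) vector("list", max(folds))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    m <- fit_learner(spec, X[!hold, , drop = FALSE], y[!hold])
    preds[hold] <- predict_learner(m, X[hold, , drop = FALSE])
    if (keep_models) models[[f]] <- m
  }
  list(pred = preds, models = models)
}

# CV RMSE curve over boosting rounds for one hyperparameter point, using
# xgboost's own CV driver with an explicit fold list.
cv_rmse_curve <- function(max_depth, eta, X, y, fold_list, max_rounds,
                          early_stop = 25L) {
  params <- xgboost::xgb.params(max_depth = max_depth, eta = eta,
                                objective = "reg:squarederror", nthread = 1)
  dm <- xgboost::xgb.DMatrix(as.matrix(X), label = y, nthread = 1)
  cv <- xgboost::xgb.cv(params = params, data = dm, nrounds = max_rounds,
                        folds = fold_list, verbose = 0,
                        early_stopping_rounds = early_stop)
  log <- cv$evaluation_log
  best <- which.min(log$test_rmse_mean)
  list(rmsecv = log$test_rmse_mean[best], nrounds = best)
}
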