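# Cross-conformal prediction engine.
#
# All training samples act as calibration samples: a 20-times-repeated
# 20-fold CV yields, per training compound, a first-run prediction y1, the
# mean mu and SD s of the repeated out-of-fold predictions, and (for the
# error-model and kNN variants) a difficulty estimate sigma. Nonconformity
# scores alpha are sorted and their upper percentiles become referent values;
# multiplying a referent by a test compound's own difficulty term gives its
# per-compound interval half-width.

fold_labels_for_repeat <- function(spec, r, n, n_folds) {
  if (r == 1L && !is.null(spec$folds)) {
    spec$folds
  } else {
    make_folds(n, n_folds, spec$seed + r)
  }
}

#' Repeated cross-validated predictions for all training samples
#'
#' Runs `n_repeats` rounds of `n_folds`-fold CV. The first repeat uses the
#' fold assignment saved on the tuned spec (so the conformal calculation and
#' the accuracy model share one split); later repeats draw fresh folds from
#' `spec$seed + repeat`. The per-fold models of the first repeat are kept:
#' their test-set prediction spread defines sigma_TEST.
#'
#' @param X numeric training descriptor matrix.
#' @param y numeric training Log(S).
#' @param spec a tuned [learner_spec()].
#' @param n_folds folds per repeat (default 20).
#' @param n_repeats repeats (default 20; >= 2).
#' @return List: `pred` (n x n_repeats out-of-fold prediction matrix), `mu`
#'   (row means), `s` (row SDs, n-1 denominator), `first` (repeat-1 column),
#'   `fold_models` (repeat-1 per-fold models), `folds` (repeat-1 labels).
#' @export
repeated_cv_predictions <- function(X, y, spec, n_folds = 20L, n_repeats = 20L) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  n <- length(y)
  if (n_folds > n) stopf("n_folds cannot exceed the number of samples")
  if (!is_count(n_repeats) || n_repeats < 2) stopf("n_repeats must be >= 2")
  P <- matrix(NA_real_, nrow = n, ncol = n_repeats)
  fold_models <- NULL
  folds1 <- NULL
  for (r in seq_len(n_repeats)) {
    folds <- fold_labels_for_repeat(spec, r, n, n_folds)
    cv <- cv_once(spec, X, y, folds, keep_models = (r == 1L))
    P[, r] <- cv$pred
    if (r == 1L) {
      fold_models <- cv$models
      folds1 <- folds
    }
  }
  list(
    pred = P,
    mu = rowMeans(P),
    s = apply(P, 1L, stats::sd),
    first = P[, 1L],
    fold_models = fold_models,
    folds = folds1
  )
}

#' Per-test-compound prediction spread, sigma_TEST
#'
#' The SD of the predictions that the saved per-fold models (each trained on
#' all but one fold) make for a test compound. Computed without any use of
#' the test compounds' experimental solubilities.
#'
#' @param fold_models list of fitted fold models (from
#'   [repeated_cv_predictions()]).
#' @param X_test numeric test descriptor matrix.
#' @return Numeric vector, one SD per test row.
#' @export
sigma_test <- function(fold_models, X_test) {
  if (!length(fold_models)) stopf("no fold models supplied")
  preds <- vapply(fold_models, function(m) predict_learner(m, X_test),
                  numeric(nrow(as.matrix(X_test))))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  apply(preds, 1L, stats::sd)
}

#' Calibration records for nonconformity scoring
#'
#' @param y experimental Log(S) of the training (= calibration) compounds.
#' @param cvp a [repeated_cv_predictions()] result.
#' @param ids optional compound identifiers.
#' @return data.frame with columns `id`, `y`, `y_hat_single` (first-run CV
#'   prediction), `mu_hat` (mean of repeats), `s` (SD of repeats).
#' @export
calibration_records <- function(y, cvp, ids = NULL) {
  n <- length(y)
  data.frame(
    id = if (is.null(ids)) sprintf("cal_%05d", seq_len(n)) else as.character(ids),
    y = y,
    y_hat_single = cvp$first,
    mu_hat = cvp$mu,
    s = cvp$s,
    stringsAsFactors = FALSE
  )
}

# Referent percentile of NC scores. Nearest-rank convention: the smallest
# score with at least q% of all scores at or below it. `interpolate = TRUE`
# switches to linear interpolation (stats::quantile type 7).
nc_referent <- function(scores, q, interpolate = FALSE) {
  if (interpolate) return(unname(stats::quantile(scores, q / 100, type = 7)))
  asc <- sort(scores)
  asc[max(1L, ceiling(q / 100 * length(asc)))]
}

new_nc_profile <- function(nc_type, beta, scores, levels, interpolate = FALSE,
                           med_sigma = NA_real_, extra = list()) {
  referents <- vapply(levels, function(q) nc_referent(scores, q, interpolate),
                      numeric(1))
  names(referents) <- as.character(levels)
  structure(
    c(list(nc_type = nc_type, beta = beta, med_sigma = med_sigma,
           scores = sort(scores, decreasing = TRUE),
           levels = levels, referents = referents), extra),
    class = "nc_profile"
  )
}

#' @export
print.nc_profile <- function(x, ...) {
  cat(sprintf("<nc_profile> %s, beta = %g; referents: %s\n", x$nc_type, x$beta,
              paste(sprintf("%s%%=%.3f", names(x$referents), x$referents),
                    collapse = ", ")))
  invisible(x)
}

check_denominator <- function(denom, ids, nc_type) {
  bad <- which(denom <= 0)
  if (length(bad)) {
    stopf(paste0(
      "degenerate normalization for %s: sigma + beta*med(sigma) <= 0 for %d ",
      "calibration sample(s) (%s%s); raise beta"),
      nc_type, length(bad),
      paste(utils::head(ids[bad], 5L), collapse = ", "),
      if (length(bad) > 5L) ", ..." else "")
  }
  invisible(denom)
}

#' Nonconformity scores and referent percentiles (AR, ARS, ARSS)
#'
#' AR is the constant-width baseline: alpha = |y - y1|, and the referents are
#' used directly as half-widths. ARS normalizes the mean-based residual by
#' the prediction-spread SD: alpha = |y - mu| / (s + beta * med(s)). ARSS is
#' identical except its numerator uses the single first-run prediction:
#' alpha = |y - y1| / (s + beta * med(s)). beta is expressed as a multiple of
#' the median calibration sigma.
#'
#' @param records a [calibration_records()] data.frame.
#' @param nc_type one of `"AR"`, `"ARS"`, `"ARSS"`.
#' @param beta sensitivity coefficient (>= 0), in units of median sigma.
#' @param levels confidence levels in percent (default `c(99, 95, 90, 80)`).
#' @param interpolate use interpolated percentiles instead of nearest-rank.
#' @return An `nc_profile` with descending-sorted scores and per-level
#'   referents.
#' @export
nc_scores <- function(records, nc_type = c("ARSS", "ARS", "AR"), beta = 0,
                      levels = c(99, 95, 90, 80), interpolate = FALSE) {
  nc_type <- match.arg(nc_type)
  if (!is.numeric(beta) || beta < 0) stopf("beta must be >= 0")
  if (nc_type == "AR") {
    alpha <- abs(records$y - records$y_hat_single)
    return(new_nc_profile("AR", beta = 0, scores = alpha, levels = levels,
                          interpolate = interpolate))
  }
  med_sigma <- stats::median(records$s)
  denom <- records$s + beta * med_sigma
  check_denominator(denom, records$id, nc_type)
  num <- if (nc_type == "ARS") abs(records$y - records$mu_hat)
         else abs(records$y - records$y_hat_single)
  new_nc_profile(nc_type, beta = beta, scores = num / denom, levels = levels,
                 interpolate = interpolate, med_sigma = med_sigma)
}

# Second-stage error-model CV across repeats. Returns per-training-sample
# and per-test-sample sigma (mean of the repeated error predictions;
# exponentiated first for the log variant).
em_sigma <- function(X, y, spec, P, n_folds, n_repeats, X_test = NULL,
                     variant = c("normal", "log"), log_floor = 1e-6) {
  variant <- match.arg(variant)
  n <- length(y)
  sig_cal <- matrix(NA_real_, nrow = n, ncol = n_repeats)
  sig_test <- if (!is.null(X_test)) {
    matrix(NA_real_, nrow = nrow(as.matrix(X_test)), ncol = 0L)
  }
  for (r in seq_len(n_repeats)) {
    folds <- fold_labels_for_repeat(spec, r, n, n_folds)
    ar <- abs(y - P[, r])
    z <- if (variant == "log") log(pmax(ar, log_floor)) else ar
    cv <- cv_once(spec, X, z, folds, keep_models = !is.null(X_test))
    e <- cv$pred
    sig_cal[, r] <- if (variant == "log") exp(e) else e
    if (!is.null(X_test)) {
      tp <- vapply(cv$models, function(m) predict_learner(m, X_test),
                   numeric(nrow(as.matrix(X_test))))
      if (is.null(dim(tp))) tp <- matrix(tp, nrow = 1L)
      if (variant == "log") tp <- exp(tp)
      sig_test <- cbind(sig_test, tp)
    }
  }
  list(
    cal = rowMeans(sig_cal),
    test = if (!is.null(X_test)) rowMeans(sig_test)
  )
}

# Mean distance from each calibration sample to its k nearest fold-training
# neighbours, averaged over the repeated CV loop; and (optionally) against
# the full training set for test samples.
knn_sigma <- function(Z, spec, k, n_folds, n_repeats, Z_test = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  D <- as.matrix(stats::dist(Z))
  acc <- matrix(NA_real_, nrow = n, ncol = n_repeats)
  for (r in seq_len(n_repeats)) {
    folds <- fold_labels_for_repeat(spec, r, n, n_folds)
    min_train <- n - max(tabulate(folds))
    if (k >= min_train) stopf("k (%d) must be smaller than the fold-training size (%d)",
                              k, min_train)
    for (f in sort(unique(folds))) {
      hold <- which(folds == f)
      keep <- which(folds != f)
      sub <- D[hold, keep, drop = FALSE]
      acc[hold, r] <- apply(sub, 1L, function(d) mean(sort(d)[seq_len(k)]))
    }
  }
  test <- NULL
  if (!is.null(Z_test)) {
    DT <- cross_dist(as.matrix(Z_test), Z)
    test <- apply(DT, 1L, function(d) mean(sort(d)[seq_len(k)]))
  }
  list(cal = rowMeans(acc), test = test)
}

#' Precomputed state for a family of cross-conformal predictors
#'
#' Runs the repeated CV once and caches everything the individual
#' nonconformity types share: the prediction matrix, the repeat-1 fold models
#' and the derived sigma_TEST, the full-training point predictions for the
#' test set, and (lazily, on first use) the error-model and kNN-distance
#' difficulty estimates. Building the state is the expensive step; deriving
#' intervals for different NC types and beta values from it is cheap.
#'
#' @param X_train,y_train training descriptors and Log(S).
#' @param X_test test descriptors (no experimental values are used).
#' @param spec tuned [learner_spec()] (its saved folds seed repeat 1).
#' @param n_folds,n_repeats CV geometry (defaults 20 and 20).
#' @param ids_test optional test compound identifiers.
#' @param Z_train,Z_test optionally, preprocessor-scaled descriptor matrices
#'   for the kNN-EuD nonconformity (defaults to `X_train`/`X_test`, which is
#'   appropriate when those are already scaled).
#' @return An object of class `conformal_state`.
#' @export
conformal_state <- function(X_train, y_train, X_test, spec,
                            n_folds = 20L, n_repeats = 20L, ids_test = NULL,
                            Z_train = NULL, Z_test = NULL) {
  X_train <- as.matrix(X_train)
  X_test <- as.matrix(X_test)
  cvp <- repeated_cv_predictions(X_train, y_train, spec, n_folds, n_repeats)
  full_model <- fit_learner(spec, X_train, y_train)
  st <- new.env(parent = emptyenv())
  st$X_train <- X_train
  st$y_train <- y_train
  st$X_test <- X_test
  st$spec <- spec
  st$n_folds <- as.integer(n_folds)
  st$n_repeats <- as.integer(n_repeats)
  st$cvp <- cvp
  st$records <- calibration_records(y_train, cvp)
  st$center <- predict_learner(full_model, X_test)
  st$sd_test <- sigma_test(cvp$fold_models, X_test)
  st$rmsecv <- sqrt(mean((y_train - cvp$first)^2))
  st$ids_test <- if (is.null(ids_test)) sprintf("test_%05d", nrow(X_test))[0] else ids_test
  if (is.null(st$ids_test) || !length(st$ids_test)) {
    st$ids_test <- sprintf("test_%05d", seq_len(nrow(X_test)))
  }
  st$Z_train <- if (is.null(Z_train)) X_train else as.matrix(Z_train)
  st$Z_test <- if (is.null(Z_test)) X_test else as.matrix(Z_test)
  st$em_cache <- list()
  st$knn_cache <- list()
  class(st) <- "conformal_state"
  st
}

#' @export
print.conformal_state <- function(x, ...) {
  cat(sprintf("<conformal_state> %d calibration, %d test compounds; %d x %d-fold CV\n",
              nrow(x$X_train), nrow(x$X_test), x$n_repeats, x$n_folds))
  invisible(x)
}

state_em <- function(st, variant) {
  key <- variant
  if (is.null(st$em_cache[[key]])) {
    st$em_cache[[key]] <- em_sigma(st$X_train, st$y_train, st$spec, st$cvp$pred,
                                   st$n_folds, st$n_repeats, st$X_test, variant)
  }
  st$em_cache[[key]]
}

state_knn <- function(st, k) {
  key <- as.character(k)
  if (is.null(st$knn_cache[[key]])) {
    st$knn_cache[[key]] <- knn_sigma(st$Z_train, st$spec, k, st$n_folds,
                                     st$n_repeats, st$Z_test)
  }
  st$knn_cache[[key]]
}

#' Error-model nonconformity profile (EM-N / EM-Log)
#'
#' A second boosted-tree model, with the same hyperparameters and the same
#' descriptors, is cross-fitted on the absolute residuals of each first-stage
#' CV run (or their logarithms for the log variant, with residuals floored at
#' `1e-6` before the log). Repeating over the CV loop gives `n_repeats` error
#' predictions per training sample and `n_repeats * n_folds` per test sample;
#' their mean (of the exponentiated predictions for the log variant) is the
#' difficulty sigma. alpha = |y - mu| / (sigma + beta * med(sigma)).
#'
#' @param state a [conformal_state()].
#' @param variant `"normal"` or `"log"`.
#' @param beta sensitivity coefficient (multiple of median sigma).
#' @param levels confidence levels in percent.
#' @param interpolate percentile convention flag.
#' @return An `nc_profile` carrying `sigma_cal` and `sigma_test`.
#' @export
nc_em <- function(state, variant = c("normal", "log"), beta = 0,
                  levels = c(99, 95, 90, 80), interpolate = FALSE) {
  variant <- match.arg(variant)
  em <- state_em(state, variant)
  med_sigma <- stats::median(em$cal)
  denom <- em$cal + beta * med_sigma
  check_denominator(denom, state$records$id,
                    if (variant == "normal") "EM-N" else "EM-Log")
  alpha <- abs(state$records$y - state$records$mu_hat) / denom
  new_nc_profile(if (variant == "normal") "EM-N" else "EM-Log",
                 beta = beta, scores = alpha, levels = levels,
                 interpolate = interpolate, med_sigma = med_sigma,
                 extra = list(sigma_cal = em$cal, sigma_test = em$test))
}

#' kNN scaled-distance nonconformity profile (kNN-EuD)
#'
#' Difficulty sigma of a calibration compound is the mean scaled Euclidean
#' distance to its k nearest fold-training neighbours, averaged over the
#' repeated CV loop; test compounds are measured against the full training
#' set. alpha = |y - mu| / (sigma + beta * med(sigma)).
#'
#' @param state a [conformal_state()] built with scaled `Z_train`/`Z_test`.
#' @param k number of neighbours (>= 1, smaller than the fold-training size).
#' @param beta sensitivity coefficient (multiple of median sigma).
#' @param levels confidence levels in percent.
#' @param interpolate percentile convention flag.
#' @return An `nc_profile` carrying `sigma_cal` and `sigma_test`.
#' @export
nc_knn_eud <- function(state, k, beta = 0, levels = c(99, 95, 90, 80),
                       interpolate = FALSE) {
  if (!is_count(k)) stopf("k must be a positive integer")
  kn <- state_knn(state, k)
  med_sigma <- stats::median(kn$cal)
  denom <- kn$cal + beta * med_sigma
  check_denominator(denom, state$records$id, "kNN-EuD")
  alpha <- abs(state$records$y - state$records$mu_hat) / denom
  new_nc_profile("kNN-EuD", beta = beta, scores = alpha, levels = levels,
                 interpolate = interpolate, med_sigma = med_sigma,
                 extra = list(sigma_cal = kn$cal, sigma_test = kn$test))
}

#' RMSE x t-value baseline profile
#'
#' Classical regression interval: half-width = t(1 - eps/2, df) * RMSECV,
#' identical for all compounds at a given level. df defaults to n_train - 1.
#'
#' @param rmsecv cross-validated RMSE of the accuracy model.
#' @param df degrees of freedom.
#' @param levels confidence levels in percent.
#' @return An `nc_profile` of type `"RMSExT"`.
#' @export
nc_rmse_t <- function(rmsecv, df, levels = c(99, 95, 90, 80)) {
  structure(
    list(nc_type = "RMSExT", beta = 0, med_sigma = NA_real_,
         scores = numeric(0), levels = levels,
         referents = stats::setNames(
           vapply(levels, function(q) {
             stats::qt(1 - (1 - q / 100) / 2, df) * rmsecv
           }, numeric(1)),
           as.character(levels)),
         rmsecv = rmsecv, df = df),
    class = "nc_profile"
  )
}

#' Interval half-widths from a nonconformity profile
#'
#' Normalized types (ARS, ARSS, EM-N, EM-Log, kNN-EuD):
#' `halfwidth = (beta * med_sigma + sigma_test) * referent(confidence)`.
#' AR and RMSExT ignore `sigma_test` and give a constant half-width.
#'
#' @param profile an `nc_profile`.
#' @param sigma_test per-test-compound difficulty term (sigma_TEST for
#'   ARS/ARSS, the error-model sigma for EM types, the kNN mean distance for
#'   kNN-EuD; any vector of the right length for the constant-width types).
#' @param confidence confidence level in percent (must be in the profile).
#' @return Numeric half-width vector aligned with `sigma_test`.
#' @export
interval_halfwidth <- function(profile, sigma_test, confidence) {
  stopifnot(inherits(profile, "nc_profile"))
  key <- as.character(confidence)
  if (!key %in% names(profile$referents)) {
    stopf("confidence %s%% not among the profile levels (%s)", key,
          paste(names(profile$referents), collapse = ", "))
  }
  ref <- profile$referents[[key]]
  n <- length(sigma_test)
  switch(profile$nc_type,
    AR = rep(ref, n),
    RMSExT = rep(ref, n),
    (profile$beta * profile$med_sigma + sigma_test) * ref
  )
}

#' Assemble symmetric prediction intervals
#'
#' `lower = center - halfwidth`, `upper = center + halfwidth`, per confidence
#' level; the point prediction sits at the interval centre.
#'
#' @param ids compound identifiers.
#' @param center point predictions.
#' @param halfwidths numeric matrix, one column per confidence level, with
#'   column names giving the level in percent (all values >= 0).
#' @param sigma_test optional per-compound difficulty values to carry along.
#' @param nc_type,beta optional provenance tags.
#' @return An object of class `interval_set`.
#' @export
build_intervals <- function(ids, center, halfwidths, sigma_test = NULL,
                            nc_type = NA_character_, beta = NA_real_) {
  halfwidths <- as.matrix(halfwidths)
  if (is.null(colnames(halfwidths))) stopf("halfwidths must have level column names")
  if (length(ids) != length(center) || nrow(halfwidths) != length(center)) {
    stopf("ids, center and halfwidths must align")
  }
  if (any(halfwidths < 0)) stopf("negative half-width")
  structure(
    list(ids = as.character(ids), center = as.numeric(center),
         sigma_test = sigma_test,
         halfwidth = halfwidths,
         lower = center - halfwidths,
         upper = center + halfwidths,
         levels = as.numeric(colnames(halfwidths)),
         nc_type = nc_type, beta = beta),
    class = "interval_set"
  )
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %s%s: %d compounds at levels %s%%\n",
              x$nc_type, if (!is.na(x$beta)) sprintf(" (beta=%g)", x$beta) else "",
              length(x$ids), paste(x$levels, collapse = "/")))
  invisible(x)
}

#' @export
as.data.frame.interval_set <- function(x, ...) {
  df <- data.frame(compound_id = x$ids, pred_logS = x$center,
                   stringsAsFactors = FALSE)
  if (!is.null(x$sigma_test)) df$sigma_test <- x$sigma_test
  for (lv in colnames(x$halfwidth)) {
    df[[paste0("hw", lv)]] <- x$halfwidth[, lv]
    df[[paste0("lo", lv)]] <- x$lower[, lv]
    df[[paste0("hi", lv)]] <- x$upper[, lv]
  }
  df
}

#' Cross-conformal prediction intervals for one configuration
#'
#' Derives the nonconformity profile of the requested type from a
#' [conformal_state()], pairs it with the matching per-test difficulty term,
#' and returns symmetric intervals around the full-training point
#' predictions.
#'
#' @param state a [conformal_state()].
#' @param nc_type one of `"AR"`, `"ARS"`, `"ARSS"`, `"EM-N"`, `"EM-Log"`,
#'   `"kNN-EuD"`, `"RMSExT"`.
#' @param beta sensitivity coefficient (multiple of median sigma; ignored for
#'   AR and RMSExT).
#' @param levels confidence levels in percent, default `c(99, 95, 90, 80)`.
#' @param k neighbours for `"kNN-EuD"`.
#' @param interpolate percentile convention flag.
#' @return An `interval_set`; the profile is attached as attribute
#'   `"profile"`.
#' @examples
#' \donttest{
#' tab <- generate_dataset(synth_spec(160, n_noise = 10, seed = 3))
#' sp <- sequential_split(tab, split_rule(4, 2))
#' spec <- learner_spec(max_depth = 2, eta = 0.3, nrounds = 30, seed = 3)
#' st <- conformal_state(tab$X[sp$train_idx, ], tab$y[sp$train_idx],
#'                       tab$X[sp$test_idx, ], spec,
#'                       n_folds = 5, n_repeats = 3)
#' ci <- conformal_intervals(st, "ARSS", beta = 0.3)
#' head(as.data.frame(ci))
#' }
#' @export
conformal_intervals <- function(state, nc_type = "ARSS", beta = 0,
                                levels = c(99, 95, 90, 80), k = NULL,
                                interpolate = FALSE) {
  stopifnot(inherits(state, "conformal_state"))
  profile <- switch(nc_type,
    "AR" = ,
    "ARS" = ,
    "ARSS" = nc_scores(state$records, nc_type, beta = beta, levels = levels,
                       interpolate = interpolate),
    "EM-N" = nc_em(state, "normal", beta = beta, levels = levels,
                   interpolate = interpolate),
    "EM-Log" = nc_em(state, "log", beta = beta, levels = levels,
                     interpolate = interpolate),
    "kNN-EuD" = {
      if (is.null(k)) stopf("nc_type 'kNN-EuD' needs k")
      nc_knn_eud(state, k = k, beta = beta, levels = levels,
                 interpolate = interpolate)
    },
    "RMSExT" = nc_rmse_t(state$rmsecv, df = length(state$y_train) - 1L,
                         levels = levels),
    stopf("unknown nc_type '%s'", nc_type)
  )
  sig <- switch(profile$nc_type,
    "AR" = ,
    "RMSExT" = rep(NA_real_, nrow(state$X_test)),
    "EM-N" = ,
    "EM-Log" = ,
    "kNN-EuD" = profile$sigma_test,
    state$sd_test
  )
  hw <- vapply(levels, function(lv) interval_halfwidth(profile, sig, lv),
               numeric(nrow(state$X_test)))
  if (is.null(dim(hw))) hw <- matrix(hw, nrow = 1L)
  colnames(hw) <- as.character(levels)
  out <- build_intervals(state$ids_test, state$center, hw,
                         sigma_test = state$sd_test,
                         nc_type = profile$nc_type, beta = profile$beta)
  attr(out, "profile") <- profile
  out
}
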