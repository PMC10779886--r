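#' Hyperparameter grid specification
#'
#' The normal grid covers `max_depth` 1..6 in steps of 1 and `eta` 0.1..1 in
#' steps of 0.1; the fine grid replaces the eta axis with 60 equidistant
#' values in (0, 0.4]. `max_rounds` caps the boosting rounds evaluated per
#' grid point (the CV picks the best round count up to the cap).
#'
#' @param max_depth_values integer vector of tree depths.
#' @param eta_values numeric vector of learning rates.
#' @param max_rounds cap on boosting rounds per grid point.
#' @param n_folds number of CV folds (default 20).
#' @param fine_grid if TRUE, use the 60-value fine eta grid.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(max_depth_values = 1:6,
                      eta_values = seq(0.1, 1, by = 0.1),
                      max_rounds = 200L,
                      n_folds = 20L,
                      fine_grid = FALSE) {
  if (isTRUE(fine_grid)) eta_values <- seq_len(60L) * 0.4 / 60
  if (!length(max_depth_values) || !all(vapply(max_depth_values, is_count, logical(1)))) {
    stopf("max_depth_values must be positive integers")
  }
  if (!length(eta_values) || any(eta_values <= 0) || any(eta_values > 1)) {
    stopf("eta_values must lie in (0, 1]")
  }
  if (!is_count(max_rounds)) stopf("max_rounds must be a positive integer")
  if (!is_count(n_folds) || n_folds < 2) stopf("n_folds must be an integer >= 2")
  structure(
    list(max_depth_values = as.integer(max_depth_values),
         eta_values = as.numeric(eta_values),
         max_rounds = as.integer(max_rounds),
         n_folds = as.integer(n_folds),
         fine_grid = isTRUE(fine_grid)),
    class = "grid_spec"
  )
}

#' Grid-search hyperparameter optimization under k-fold CV
#'
#' Evaluates every (max_depth, eta) grid point with the same k-fold CV split
#' and returns the point minimizing RMSECV, with the best round count up to
#' the cap. Ties break deterministically: smallest nrounds, then smallest
#' max_depth, then smallest eta. The winning fold assignment is saved on the
#' returned spec and reused by all downstream conformal computations.
#'
#' @param X numeric descriptor matrix.
#' @param y numeric response (finite).
#' @param grid a [grid_spec()].
#' @param seed integer seed for the fold shuffle.
#' @return A [learner_spec()] carrying `folds`, plus attributes `rmsecv` and
#'   `grid_results` (the full evaluation table).
#' @export
grid_search_cv <- function(X, y, grid = grid_spec(), seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  X <- as.matrix(X)
  if (any(!is.finite(y))) stopf("response contains non-finite values")
  if (nrow(X) < grid$n_folds) stopf("need at least n_folds samples")
  folds <- make_folds(nrow(X), grid$n_folds, seed)
  fold_list <- split(seq_len(nrow(X)), folds)
  pts <- expand.grid(max_depth = grid$max_depth_values, eta = grid$eta_values,
                     KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(pts)), function(i) {
    cv_rmse_curve(pts$max_depth[i], pts$eta[i], X, y, fold_list, grid$max_rounds)
  })
  tab <- data.frame(
    max_depth = pts$max_depth, eta = pts$eta,
    nrounds = vapply(res, `[[`, numeric(1), "nrounds"),
    rmsecv = vapply(res, `[[`, numeric(1), "rmsecv")
  )
  ord <- order(tab$rmsecv, tab$nrounds, tab$max_depth, tab$eta)
  win <- tab[ord[1L], ]
  spec <- learner_spec(max_depth = win$max_depth, eta = win$eta,
                       nrounds = win$nrounds, folds = folds, seed = seed)
  attr(spec, "rmsecv") <- win$rmsecv
  attr(spec, "grid_results") <- tab
  spec
}

# Greedy correlation filter: walk names in rank order, drop any descriptor
# whose absolute Pearson correlation (on training rows) with an already-kept
# descriptor exceeds the threshold.
filter_correlated <- function(ranked_names, X, corr_threshold) {
  kept <- character(0)
  for (nm in ranked_names) {
    if (!length(kept)) {
      kept <- nm
      next
    }
    r <- suppressWarnings(abs(stats::cor(X[, nm], X[, kept, drop = FALSE])))
    r[is.na(r)] <- 0
    if (all(r <= corr_threshold)) kept <- c(kept, nm)
  }
  kept
}

inner_grid_for <- function(spec, grid, inner_grid) {
  switch(inner_grid,
    full = grid,
    fixed = grid_spec(max_depth_values = spec$max_depth, eta_values = spec$eta,
                      max_rounds = grid$max_rounds, n_folds = grid$n_folds),
    reduced = {
      depths <- intersect(spec$max_depth + (-1:1), 1:6)
      grid_spec(max_depth_values = depths, eta_values = spec$eta,
                max_rounds = grid$max_rounds, n_folds = grid$n_folds)
    },
    stopf("unknown inner_grid '%s'", inner_grid)
  )
}

#' Forward-stepwise top-importance (FSTI) variable selection
#'
#' Ranks all descriptors by the importance of a grid-optimized boosted-tree
#' model, optionally removes descriptors correlated above `corr_threshold`
#' with a higher-ranked kept descriptor, then evaluates nested prefixes of
#' the ranking with an inner grid-searched CV: every prefix of size 3..m is
#' scored, and beyond m the forward addition continues one descriptor at a
#' time until the RMSECV of a new step exceeds that of the previous step.
#' The selected set is the prefix at the global RMSECV minimum.
#'
#' The inner grid defaults to a reduced neighbourhood of the all-variable
#' winner (its max_depth +/- 1 at its eta); `inner_grid = "full"` re-searches
#' the full grid at every step and `"fixed"` keeps the winner's point.
#'
#' @param X numeric descriptor matrix with named columns.
#' @param y numeric response.
#' @param m forward-addition cap before the stop rule engages (default 30).
#' @param corr_threshold optional absolute-correlation cut (e.g. 0.9).
#' @param inner_folds folds of the inner CV (default 5).
#' @param seed integer seed.
#' @param grid [grid_spec()] for the initial all-variable tuning.
#' @param inner_grid one of "reduced", "fixed", "full".
#' @return An object of class `selection_result`: `ranked_names`,
#'   `selected_names`, `rmsecv_path` (named by prefix size), `stop_index`,
#'   `tuned_spec`, `importance`.
#' @export
fsti_select <- function(X, y, m = 30L, corr_threshold = NULL,
                        inner_folds = 5L, seed = 1L, grid = grid_spec(),
                        inner_grid = c("reduced", "fixed", "full")) {
  inner_grid <- match.arg(inner_grid)
  X <- as.matrix(X)
  if (!is_count(m) || m < 3) stopf("m must be an integer >= 3")
  if (nrow(X) < inner_folds) stopf("need at least inner_folds samples")
  tuned <- grid_search_cv(X, y, grid = grid, seed = seed)
  full_model <- fit_learner(tuned, X, y)
  imp <- importance_ranking(full_model)
  ranked <- imp$name
  usable <- ranked
  if (!is.null(corr_threshold)) {
    usable <- filter_correlated(ranked, X, corr_threshold)
  }
  if (length(usable) < 3L) stopf("fewer than 3 usable descriptors after filtering")

  igrid <- inner_grid_for(tuned, grid, inner_grid)
  inner_fold_labels <- make_folds(nrow(X), inner_folds, seed + 1L)
  fold_list <- split(seq_len(nrow(X)), inner_fold_labels)
  score_prefix <- function(size) {
    Xs <- X[, usable[seq_len(size)], drop = FALSE]
    pts <- expand.grid(max_depth = igrid$max_depth_values,
                       eta = igrid$eta_values, KEEP.OUT.ATTRS = FALSE)
    best <- Inf
    for (i in seq_len(nrow(pts))) {
      r <- cv_rmse_curve(pts$max_depth[i], pts$eta[i], Xs, y, fold_list,
                         igrid$max_rounds)
      if (r$rmsecv < best) best <- r$rmsecv
    }
    best
  }

  max_size <- length(usable)
  sizes <- seq(3L, min(m, max_size))
  path <- vapply(sizes, score_prefix, numeric(1))
  # beyond m: keep adding while RMSECV still improves on the previous step
  size <- min(m, max_size)
  while (size < max_size) {
    nxt <- score_prefix(size + 1L)
    sizes <- c(sizes, size + 1L)
    path <- c(path, nxt)
    if (nxt > path[length(path) - 1L]) break
    size <- size + 1L
  }
  names(path) <- sizes
  stop_index <- which.min(path)
  selected <- usable[seq_len(sizes[stop_index])]
  structure(
    list(ranked_names = ranked, selected_names = selected,
         rmsecv_path = path, stop_index = unname(stop_index),
         tuned_spec = tuned, importance = imp,
         usable_names = usable),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d of %d descriptors selected (RMSECV %.4f at prefix %s)\n",
              length(x$selected_names), length(x$ranked_names),
              min(x$rmsecv_path), names(x$rmsecv_path)[x$stop_index]))
  invisible(x)
}

#' Percentage of predictions within a Log(S) tolerance
#'
#' Inclusive inequality: a residual exactly at the threshold counts as within.
#'
#' @param residuals numeric vector of residuals (signed or absolute).
#' @param threshold tolerance in Log(S) units (e.g. 0.7 or 1.0).
#' @return Percentage in 0..100.
#' @export
pct_within <- function(residuals, threshold) {
  100 * mean(abs(residuals) <= threshold)
}

#' Accuracy metrics of a tuned model on train (CV) and test sets
#'
#' RMSECV and CV-set R2 come from the saved fold assignment of the spec;
#' RMSEV and V-set R2 from a full-training fit applied to the test set.
#' `%LogS +/- 0.7` and `%LogS +/- 1.0` are the percentages of predictions
#' within 0.7 and 1.0 Log(S) units of experiment.
#'
#' @param spec a tuned [learner_spec()] (with saved folds, else folds are
#'   drawn from its seed).
#' @param X_train,y_train training descriptors and Log(S).
#' @param X_test,y_test test descriptors and Log(S).
#' @param n_folds folds used if the spec carries no assignment.
#' @return List of metrics: `rmsecv`, `rmsev`, `r2_cv`, `r2_v`,
#'   `pct07_cv`, `pct10_cv`, `pct07_v`, `pct10_v`.
#' @export
evaluate_model <- function(spec, X_train, y_train, X_test, y_test,
                           n_folds = 20L) {
  stopifnot(inherits(spec, "learner_spec"))
  if (!length(y_test)) stopf("empty test set")
  folds <- spec$folds
  if (is.null(folds)) folds <- make_folds(length(y_train), n_folds, spec$seed)
  cv_pred <- cv_once(spec, X_train, y_train, folds)$pred
  model <- fit_learner(spec, X_train, y_train)
  test_pred <- predict_learner(model, X_test)
  r2 <- function(obs, pred) 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  rcv <- y_train - cv_pred
  rv <- y_test - test_pred
  list(
    rmsecv = sqrt(mean(rcv^2)),
    rmsev = sqrt(mean(rv^2)),
    r2_cv = r2(y_train, cv_pred),
    r2_v = r2(y_test, test_pred),
    pct07_cv = pct_within(rcv, 0.7),
    pct10_cv = pct_within(rcv, 1.0),
    pct07_v = pct_within(rv, 0.7),
    pct10_v = pct_within(rv, 1.0),
    cv_pred = cv_pred,
    test_pred = test_pred
  )
}
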