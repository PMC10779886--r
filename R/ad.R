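# kNN applicability domain on training-scaled descriptors.
#
# The per-training-sample threshold rule is isolated in ad_thresholds() so it
# can be swapped without touching the decision logic.

# For each training sample: mean Euclidean distance to its k nearest training
# neighbours, globally capped at RefVal = Q3 + 1.5*IQR of those mean-kNN
# distances. Ties in neighbour ranking break by row order (deterministic).
ad_thresholds <- function(D, k) {
  n <- nrow(D)
  mean_knn <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    mean(d[order(d)][seq_len(k)])
  }, numeric(1))
  qs <- stats::quantile(mean_knn, c(0.25, 0.75), names = FALSE)
  ref_val <- qs[2L] + 1.5 * (qs[2L] - qs[1L])
  list(thresholds = pmin(mean_knn, ref_val), ref_val = ref_val,
       mean_knn = mean_knn)
}

#' Fit a k-nearest-neighbour applicability domain
#'
#' The AD is defined entirely by the training set: each training sample i gets
#' a distance threshold derived from the distribution of mean k-nearest-
#' neighbour distances (mean distance to the k nearest training neighbours,
#' capped at `Q3 + 1.5*IQR` of that distribution). A query compound is inside
#' the AD iff it lies within the threshold of at least one training sample.
#'
#' @param Z_train numeric matrix of training descriptors already scaled with
#'   the training [fit_preprocessor()] model (>= 3 rows).
#' @param k_fraction fraction of the training set used as k, in (0, 1);
#'   `k = round_half_up(k_fraction * n_train)`, floored at 1. 0.375 is the
#'   default; 0.05 is the strict variant used for split vetting.
#' @return An object of class `ad_model` with `Z_train`, `k_neighbors`,
#'   `thresholds`, `ref_val`.
#' @export
fit_ad <- function(Z_train, k_fraction = 0.375) {
  Z_train <- as.matrix(Z_train)
  n <- nrow(Z_train)
  if (n < 3L) stopf("need at least 3 training rows to fit an AD")
  if (!is.numeric(k_fraction) || length(k_fraction) != 1L ||
      k_fraction <= 0 || k_fraction >= 1) {
    stopf("k_fraction must lie strictly between 0 and 1")
  }
  k <- max(1L, as.integer(round_half_up(k_fraction * n)))
  if (k >= n) k <- n - 1L
  D <- as.matrix(stats::dist(Z_train))
  th <- ad_thresholds(D, k)
  structure(
    list(Z_train = Z_train, k_neighbors = k, thresholds = th$thresholds,
         ref_val = th$ref_val),
    class = "ad_model"
  )
}

#' Decide AD membership for query compounds
#'
#' A query is inside the AD iff its Euclidean distance to at least one
#' training sample i is `<= thresholds[i]`. Queries must be scaled with the
#' same training preprocessing model as `Z_train`.
#'
#' @param model an [fit_ad()] result.
#' @param Z_query scaled numeric matrix with the same columns as the training
#'   matrix.
#' @return Logical vector aligned with the query rows, with attribute
#'   `min_distance` (distance to the nearest training sample).
#' @export
check_ad <- function(model, Z_query) {
  stopifnot(inherits(model, "ad_model"))
  Z_query <- as.matrix(Z_query)
  if (ncol(Z_query) != ncol(model$Z_train)) {
    stopf("query has %d columns but the AD was fitted on %d",
          ncol(Z_query), ncol(model$Z_train))
  }
  if (!is.null(colnames(Z_query)) && !is.null(colnames(model$Z_train)) &&
      !identical(colnames(Z_query), colnames(model$Z_train))) {
    stopf("query column names do not match the AD training columns")
  }
  D <- cross_dist(Z_query, model$Z_train)
  inside <- apply(D, 1L, function(d) any(d <= model$thresholds))
  attr(inside, "min_distance") <- apply(D, 1L, min)
  inside
}

#' Percentage of query compounds outside the AD
#'
#' @inheritParams check_ad
#' @return `100 * (# outside) / (# queries)`.
#' @export
ad_coverage <- function(model, Z_query) {
  Z_query <- as.matrix(Z_query)
  if (nrow(Z_query) == 0L) stopf("empty query set")
  inside <- check_ad(model, Z_query)
  100 * sum(!inside) / length(inside)
}

#' Project training and query descriptors onto training principal components
#'
#' PCA is fitted on the training matrix only; query rows are centred with the
#' training means and projected onto the same axes. Diagnostic use only: the
#' AD decision never uses these coordinates.
#'
#' @param Z_train scaled training matrix.
#' @param Z_query scaled query matrix with the same columns.
#' @param n_components number of components to keep (default 3).
#' @return List with score matrices `train` and `query` and the `rotation`.
#' @export
pca_projection <- function(Z_train, Z_query, n_components = 3L) {
  Z_train <- as.matrix(Z_train)
  Z_query <- as.matrix(Z_query)
  max_rank <- min(nrow(Z_train) - 1L, ncol(Z_train))
  if (!is_count(n_components) || n_components > max_rank) {
    stopf("n_components must be a positive integer <= %d", max_rank)
  }
  pr <- stats::prcomp(Z_train, center = TRUE, scale. = FALSE)
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  qc <- sweep(Z_query, 2L, pr$center, "-") %*% rot
  list(
    train = pr$x[, seq_len(n_components), drop = FALSE],
    query = qc,
    rotation = rot
  )
}
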