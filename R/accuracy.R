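# Accuracy classes and the percentile-based overall accuracy estimate for
# screening sets without experimental solubilities.

ACC_CLASS_LABELS <- c("acc.>90%", "80-90%", "70-80%", "acc.<70%")

#' Assign the four accuracy classes from interval half-widths
#'
#' A compound whose 90%-confidence half-width is below 1 Log(S) is estimated
#' to be predicted within +/- 1 Log(S) with more than 90% probability
#' (class `acc.>90%`); failing that, half-widths below 1 at the 80% and 70%
#' levels give the `80-90%` and `70-80%` classes; compounds whose 70% interval
#' is still wider than 1 Log(S) fall in `acc.<70%`.
#'
#' @param intervals an `interval_set` containing the 70, 80 and 90% levels.
#' @param hw_threshold the half-width boundary in Log(S) units (default 1).
#' @return data.frame of class `accuracy_class_table`: `compound_id`,
#'   `accuracy_class` (factor over the four labels), `hw80`.
#' @export
classify_compounds <- function(intervals, hw_threshold = 1) {
  stopifnot(inherits(intervals, "interval_set"))
  need <- c("90", "80", "70")
  missing_lv <- setdiff(need, colnames(intervals$halfwidth))
  if (length(missing_lv)) {
    stopf("interval set lacks the %s%% level(s)", paste(missing_lv, collapse = ", "))
  }
  hw90 <- intervals$halfwidth[, "90"]
  hw80 <- intervals$halfwidth[, "80"]
  hw70 <- intervals$halfwidth[, "70"]
  cls <- ifelse(hw90 < hw_threshold, ACC_CLASS_LABELS[1L],
         ifelse(hw80 < hw_threshold, ACC_CLASS_LABELS[2L],
         ifelse(hw70 < hw_threshold, ACC_CLASS_LABELS[3L],
                ACC_CLASS_LABELS[4L])))
  out <- data.frame(
    compound_id = intervals$ids,
    accuracy_class = factor(cls, levels = ACC_CLASS_LABELS),
    hw80 = hw80,
    stringsAsFactors = FALSE
  )
  class(out) <- c("accuracy_class_table", class(out))
  out
}

#' Percentile-based overall accuracy profile
#'
#' For each confidence level, the fraction of compounds whose interval
#' half-width is below 1 Log(S) is recorded; that fraction of the set is
#' predicted within +/- 1 Log(S) with at least that level's probability.
#' Consecutive levels then bound accuracy bands: the band between levels c1 >
#' c2 holds the compounds crossing the 1 Log(S) line between them (fraction =
#' difference of the two cumulative fractions) and is assigned the midpoint
#' accuracy (c1 + c2) / 2. The overall accuracy estimate is the
#' fraction-weighted average of the band accuracies.
#'
#' If no compound is below the threshold at any level, the estimate falls
#' back to the confidence level at which the mean half-width equals
#' 1 Log(S) (linear interpolation over the supplied levels), with a warning.
#'
#' @param intervals an `interval_set` spanning at least two confidence
#'   levels, or NULL when `fractions` are supplied directly.
#' @param levels confidence levels (percent) to profile; defaults to the
#'   levels present in the interval set.
#' @param fractions optional cumulative fractions (one per level) of
#'   compounds with half-width under the threshold, overriding the
#'   computation from `intervals`.
#' @param hw_threshold half-width boundary in Log(S) units (default 1).
#' @return List of class `accuracy_profile`: `levels`, `fractions`,
#'   `band_accuracy` (percent), `band_fraction`, `overall_accuracy`
#'   (percent).
#' @examples
#' accuracy_profile(levels = c(92, 90, 80, 70),
#'                  fractions = c(0.04, 0.09, 0.73, 0.96))$overall_accuracy
#' @export
accuracy_profile <- function(intervals = NULL, levels = NULL, fractions = NULL,
                             hw_threshold = 1) {
  if (is.null(fractions)) {
    stopifnot(inherits(intervals, "interval_set"))
    if (is.null(levels)) levels <- intervals$levels
    levels <- sort(as.numeric(levels), decreasing = TRUE)
    missing_lv <- setdiff(as.character(levels), colnames(intervals$halfwidth))
    if (length(missing_lv)) {
      stopf("interval set lacks the %s%% level(s)", paste(missing_lv, collapse = ", "))
    }
    fractions <- vapply(as.character(levels), function(lv) {
      mean(intervals$halfwidth[, lv] < hw_threshold)
    }, numeric(1))
  } else {
    if (is.null(levels) || length(levels) != length(fractions)) {
      stopf("levels and fractions must align")
    }
    ord <- order(levels, decreasing = TRUE)
    levels <- as.numeric(levels)[ord]
    fractions <- as.numeric(fractions)[ord]
  }
  if (length(levels) < 2L) stopf("need at least two confidence levels")
  if (is.unsorted(fractions)) {
    stopf("cumulative fractions must be non-decreasing as confidence decreases")
  }
  band_fraction <- diff(fractions)
  band_accuracy <- (utils::head(levels, -1L) + utils::tail(levels, -1L)) / 2
  if (sum(band_fraction) <= 0) {
    if (max(fractions) == 0) {
      if (is.null(intervals)) {
        stopf("degenerate profile: no compound under the half-width threshold")
      }
      warning("no compound under the half-width threshold at any level; ",
              "falling back to the mean-half-width estimate", call. = FALSE)
      mean_hw <- vapply(as.character(levels), function(lv) {
        mean(intervals$halfwidth[, lv])
      }, numeric(1))
      overall <- stats::approx(mean_hw, levels, xout = hw_threshold, rule = 2)$y
    } else {
      # everyone already below the threshold at the top level
      overall <- levels[1L]
    }
  } else {
    overall <- sum(band_accuracy * band_fraction) / sum(band_fraction)
  }
  structure(
    list(levels = levels, fractions = fractions,
         band_accuracy = band_accuracy, band_fraction = band_fraction,
         overall_accuracy = overall),
    class = "accuracy_profile"
  )
}

#' @export
print.accuracy_profile <- function(x, ...) {
  cat(sprintf("<accuracy_profile> overall %%LogS+/-1 estimate: %.1f%%\n",
              x$overall_accuracy))
  for (i in seq_along(x$band_fraction)) {
    cat(sprintf("  band %g-%g%%: accuracy %.1f%%, fraction %.3f\n",
                x$levels[i + 1L], x$levels[i], x$band_accuracy[i],
                x$band_fraction[i]))
  }
  invisible(x)
}

#' Linear combination of model accuracies
#'
#' Count-weighted mean of per-model accuracy estimates, used to merge the
#' accuracy of several models each covering a different part of a screening
#' set.
#'
#' @param counts positive compound counts (or fractions) per model.
#' @param accuracies accuracy estimates in percent, aligned with `counts`.
#' @return Combined accuracy in percent.
#' @examples
#' combine_models(c(10413, 717), c(82.8, 63.7))  # 81.6
#' @export
combine_models <- function(counts, accuracies) {
  if (length(counts) != length(accuracies)) {
    stopf("counts and accuracies must have equal length")
  }
  if (!length(counts) || any(counts <= 0)) stopf("counts must be positive")
  sum(counts * accuracies) / sum(counts)
}

#' Export per-compound predictions with accuracy classes
#'
#' Writes the seven-column screening-set layout: identifier, SMILES,
#' molecular weight, predicted Log(S), model tag, 80%-confidence half-width,
#' and accuracy class.
#'
#' @param ids,smiles,weights,preds aligned per-compound vectors.
#' @param model_tag model label (single string or per-compound vector).
#' @param hw80 80%-confidence interval half-widths.
#' @param class_labels accuracy classes (values from the four class labels).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_predictions <- function(ids, smiles, weights, preds, model_tag, hw80,
                               class_labels, path) {
  n <- length(ids)
  class_labels <- as.character(class_labels)
  if (!all(class_labels %in% ACC_CLASS_LABELS)) {
    stopf("class_labels must be one of: %s", paste(ACC_CLASS_LABELS, collapse = ", "))
  }
  df <- data.frame(
    id = ids, smiles = smiles, mol_weight = weights, pred_logS = preds,
    model_tag = rep_len(model_tag, n), hw80 = hw80,
    accuracy_class = class_labels, stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
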