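# Interval validity (error rates, t-test validation) and efficiency
# (half-width statistics, gain vs the constant-width AR baseline).

#' Empirical error rate of prediction intervals
#'
#' A compound is a misclassification at a level iff its experimental value
#' lies strictly outside the interval (boundary values count as inside).
#'
#' @param intervals an `interval_set`.
#' @param y_true experimental Log(S), aligned with the interval rows.
#' @param ids optional identifiers to check alignment against.
#' @return Named numeric vector of per-level error fractions (0..1), with the
#'   per-level 0/1 outside flags attached as attribute `"outside"`.
#' @export
error_rate <- function(intervals, y_true, ids = NULL) {
  stopifnot(inherits(intervals, "interval_set"))
  if (length(y_true) != length(intervals$ids)) {
    stopf("y_true has %d values but the interval set has %d compounds",
          length(y_true), length(intervals$ids))
  }
  if (!is.null(ids) && !identical(as.character(ids), intervals$ids)) {
    stopf("compound ids do not match the interval set")
  }
  outside <- (y_true < intervals$lower) | (y_true > intervals$upper)
  rates <- colMeans(outside)
  names(rates) <- colnames(intervals$halfwidth)
  attr(rates, "outside") <- outside
  rates
}

#' Equal-variance t-test validation of an error rate
#'
#' Compares the observed outside/inside dummy vector with an expected vector
#' of the same length containing exactly `round_half_up(n * (1 - confidence))`
#' ones, using an equal-variance two-sample t-test. The configuration fails
#' validation iff p < alpha (default 0.01).
#'
#' @param outside_flags 0/1 (or logical) vector, 1 = outside the interval.
#' @param confidence confidence level as a fraction strictly in (0, 1).
#' @param alpha significance threshold (default 0.01).
#' @return List: `p_value`, `passed`, `error_rate`, `expected_rate`.
#' @export
validate_error_rate <- function(outside_flags, confidence, alpha = 0.01) {
  flags <- as.numeric(outside_flags)
  n <- length(flags)
  if (n < 2L) stopf("need at least 2 test samples")
  if (confidence <= 0 || confidence >= 1) {
    stopf("confidence must lie strictly between 0 and 1")
  }
  n_exp <- round_half_up(n * (1 - confidence))
  expected <- c(rep(1, n_exp), rep(0, n - n_exp))
  p <- if (stats::sd(flags) == 0 && stats::sd(expected) == 0) {
    if (mean(flags) == mean(expected)) 1 else 0
  } else {
    stats::t.test(flags, expected, var.equal = TRUE)$p.value
  }
  list(p_value = p, passed = p >= alpha,
       error_rate = mean(flags), expected_rate = 1 - confidence)
}

#' Per-level validation report for an interval set
#'
#' @inheritParams error_rate
#' @param alpha significance threshold of the t-test (default 0.01).
#' @return data.frame with one row per confidence level: `level`,
#'   `error_rate`, `expected_rate`, `p_value`, `passed`.
#' @export
validation_report <- function(intervals, y_true, alpha = 0.01) {
  rates <- error_rate(intervals, y_true)
  outside <- attr(rates, "outside")
  rows <- lapply(colnames(outside), function(lv) {
    v <- validate_error_rate(outside[, lv], as.numeric(lv) / 100, alpha)
    data.frame(level = as.numeric(lv), error_rate = v$error_rate,
               expected_rate = v$expected_rate, p_value = v$p_value,
               passed = v$passed)
  })
  do.call(rbind, rows)
}

#' Efficiency of conformal configurations against the AR baseline
#'
#' For every configuration and confidence level: the median (Q2) and mean
#' half-width, the efficiency gain `Q2(AR) / Q2(CP) - 1`, and a two-sample
#' t-test (unpaired by default) of the configuration's half-widths against
#' the AR half-widths.
#'
#' @param intervals_by_config named list of `interval_set`s (same test
#'   compounds throughout).
#' @param ar_intervals the AR baseline `interval_set`.
#' @param paired use a paired t-test instead of the unpaired default.
#' @return data.frame of class `efficiency_report`: `config`, `level`,
#'   `median_hw`, `mean_hw`, `gain_vs_ar`, `p_value_vs_ar`.
#' @export
efficiency <- function(intervals_by_config, ar_intervals, paired = FALSE) {
  stopifnot(inherits(ar_intervals, "interval_set"))
  if (!length(intervals_by_config)) stopf("no interval sets supplied")
  if (is.null(names(intervals_by_config)) || any(!nzchar(names(intervals_by_config)))) {
    stopf("intervals_by_config must be a named list")
  }
  n <- length(ar_intervals$ids)
  rows <- list()
  for (cfg in names(intervals_by_config)) {
    iv <- intervals_by_config[[cfg]]
    if (length(iv$ids) != n) stopf("config '%s' covers different test compounds", cfg)
    for (lv in colnames(iv$halfwidth)) {
      if (!lv %in% colnames(ar_intervals$halfwidth)) {
        stopf("the AR baseline lacks the %s%% level present in config '%s'",
              lv, cfg)
      }
      hw <- iv$halfwidth[, lv]
      ar_hw <- ar_intervals$halfwidth[, lv]
      p <- if (stats::sd(hw) == 0 && stats::sd(ar_hw) == 0) {
        if (stats::median(hw) == stats::median(ar_hw)) 1 else 0
      } else if (paired) {
        stats::t.test(hw, ar_hw, paired = TRUE)$p.value
      } else {
        stats::t.test(hw, ar_hw, var.equal = FALSE)$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        config = cfg, level = as.numeric(lv),
        median_hw = stats::median(hw), mean_hw = mean(hw),
        gain_vs_ar = stats::median(ar_hw) / stats::median(hw) - 1,
        p_value_vs_ar = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("efficiency_report", class(out))
  out
}

#' Select the optimal conformal configuration
#'
#' Per confidence level, the winner is the configuration with minimal mean
#' half-width among those passing validation at that level. The overall
#' winner minimizes the unweighted average of the eight statistics (mean and
#' median half-width at each of the four levels) among configurations that
#' pass validation at every level. The result does not depend on the order
#' in which configurations are supplied (ties break alphabetically).
#'
#' @param efficiency_report an [efficiency()] result.
#' @param validation_reports named list (same config names) of
#'   [validation_report()] data.frames.
#' @return List: `per_level` (named character vector, level -> config) and
#'   `overall` (single config name, or NA if none passes everywhere).
#' @export
select_optimal_cp <- function(efficiency_report, validation_reports) {
  eff <- as.data.frame(efficiency_report)
  cfgs <- sort(unique(eff$config))
  levels <- sort(unique(eff$level), decreasing = TRUE)
  passes <- function(cfg, lv) {
    vr <- validation_reports[[cfg]]
    if (is.null(vr)) return(FALSE)
    any(vr$level == lv & vr$passed)
  }
  per_level <- stats::setNames(rep(NA_character_, length(levels)),
                               as.character(levels))
  for (lv in levels) {
    ok <- cfgs[vapply(cfgs, passes, logical(1), lv = lv)]
    if (!length(ok)) next
    sub <- eff[eff$config %in% ok & eff$level == lv, ]
    sub <- sub[order(sub$mean_hw, sub$config), ]
    per_level[as.character(lv)] <- sub$config[1L]
  }
  if (all(is.na(per_level))) stopf("no configuration passes validation at any level")
  all_pass <- cfgs[vapply(cfgs, function(cfg) {
    all(vapply(levels, passes, logical(1), cfg = cfg))
  }, logical(1))]
  overall <- NA_character_
  if (length(all_pass)) {
    avg8 <- vapply(all_pass, function(cfg) {
      sub <- eff[eff$config == cfg, ]
      mean(c(sub$mean_hw, sub$median_hw))
    }, numeric(1))
    overall <- all_pass[order(avg8, all_pass)][1L]
  }
  list(per_level = per_level, overall = overall)
}

#' Correlation between interval half-widths and absolute residuals
#'
#' The informativeness check: a valid normalized conformal predictor should
#' give wider intervals to compounds it predicts worse. Undefined for
#' constant-width configurations (AR, RMSExT), which carry no per-compound
#' information; these raise an error.
#'
#' @param intervals an `interval_set`.
#' @param y_true experimental Log(S).
#' @param level confidence level in percent (default 90).
#' @return List: `r` (Pearson correlation), `r2`, `p_value` (two-sided).
#' @export
residual_interval_correlation <- function(intervals, y_true, level = 90) {
  stopifnot(inherits(intervals, "interval_set"))
  key <- as.character(level)
  if (!key %in% colnames(intervals$halfwidth)) {
    stopf("level %s%% not present in the interval set", key)
  }
  hw <- intervals$halfwidth[, key]
  if (stats::sd(hw) == 0) {
    stopf("half-widths are constant (%s): the correlation with residuals is undefined",
          intervals$nc_type)
  }
  ar <- abs(y_true - intervals$center)
  ct <- stats::cor.test(ar, hw, method = "pearson")
  list(r = unname(ct$estimate), r2 = unname(ct$estimate)^2,
       p_value = ct$p.value)
}
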