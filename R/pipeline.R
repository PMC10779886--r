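# End-to-end orchestration: split -> preprocess -> AD -> (optional FSTI) ->
# tune -> conformal -> validate -> classify, from a single configuration.

RUN_CONFIG_KEYS <- c("train_table", "target_column", "id_column", "simulate",
                     "split", "ad", "selection", "grid", "conformal",
                     "validation", "out_dir", "seed")

#' Build and validate a pipeline run configuration
#'
#' Accepts a list (or a path to a JSON file with the same shape), fills in
#' defaults, and rejects unknown keys before any computation starts. The
#' effective configuration is serialized into the run directory, so a run is
#' fully reproducible from its `config.json` and seed.
#'
#' @param config list or JSON file path. Recognized keys:
#'   `train_table` (CSV path) or `simulate` (list of [synth_spec()]
#'   arguments); `target_column`, `id_column`; `split` (period, offsets);
#'   `ad` (k_fraction); `selection` (enabled, m, corr_threshold, folds);
#'   `grid` (max_depth, eta, max_rounds, n_folds); `conformal` (nc_types,
#'   betas, levels, n_repeats, knn_k); `validation` (alpha); `out_dir`;
#'   `seed`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  defaults <- list(
    target_column = "logS", id_column = "compound_id",
    split = list(period = 6, offsets = 2),
    ad = list(k_fraction = 0.375),
    selection = list(enabled = FALSE, m = 30, corr_threshold = NULL, folds = 5),
    grid = list(max_depth = c(2, 3), eta = c(0.1, 0.3), max_rounds = 60,
                n_folds = 10),
    conformal = list(nc_types = c("ARSS", "AR"), betas = c(0, 0.2, 0.5, 1.0),
                     levels = c(99, 95, 90, 80, 70), n_repeats = 10,
                     knn_k = NULL),
    validation = list(alpha = 0.01),
    out_dir = "confsol_run", seed = 1
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]])) {
      for (kk in names(defaults[[k]])) {
        if (is.null(config[[k]][[kk]])) config[[k]][[kk]] <- defaults[[k]][[kk]]
      }
    }
  }
  if (is.null(config$train_table) && is.null(config$simulate)) {
    stopf("config needs either train_table or simulate")
  }
  if (any(config$conformal$betas < 0)) stopf("conformal betas must be >= 0")
  bad <- setdiff(config$conformal$nc_types,
                 c("AR", "ARS", "ARSS", "EM-N", "EM-Log", "kNN-EuD", "RMSExT"))
  if (length(bad)) stopf("unknown nc_types: %s", paste(bad, collapse = ", "))
  if (!is_count(config$seed) && config$seed != 0) stopf("seed must be an integer")
  structure(config, class = "run_config")
}

pipeline_log <- function(log_path, stage, ...) {
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(sprintf(...), collapse = " "))
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  invisible(line)
}

#' Run the full informative-solubility pipeline
#'
#' Executes the four-stage strategy: (a) accuracy modelling (grid-tuned
#' boosted trees, optional FSTI variable selection), (b) applicability-domain
#' coverage of the test side, (c) cross-conformal calibration plus error-rate
#' validation for every requested (NC type, beta) configuration, and
#' (d) accuracy classification and the overall accuracy profile using the
#' winning configuration. Classification is skipped (with an explanatory log
#' entry) if no configuration passes validation at any level.
#'
#' Artifacts written to the run directory: `config.json`, `intervals.csv`
#' (winning configuration), `report.json`, `classes.csv`, `profile.json`,
#' `run.log`.
#'
#' @param config a [run_config()] (or anything it accepts).
#' @return The run directory path, invisibly; the parsed report as attribute
#'   `"report"`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  jsonlite::write_json(unclass(config), file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  seed <- as.integer(config$seed)

  tab <- if (!is.null(config$train_table)) {
    read_descriptor_table(config$train_table, id_column = config$id_column,
                          target_column = config$target_column)
  } else {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- seed
    generate_dataset(do.call(synth_spec, sim_args))
  }
  pipeline_log(log_path, "data", "%d compounds, %d descriptors",
               length(tab$ids), ncol(tab$X))

  sp <- sequential_split(tab, split_rule(config$split$period, config$split$offsets))
  train <- subset_table(tab, sp$train_idx)
  test <- subset_table(tab, sp$test_idx)
  pipeline_log(log_path, "split", "train %d / test %d (period %d, offsets %s)",
               length(train$ids), length(test$ids), config$split$period,
               paste(config$split$offsets, collapse = ","))

  prep <- fit_preprocessor(train)
  Z_train <- apply_preprocessor(prep, train)
  Z_test <- apply_preprocessor(prep, test)
  ad <- fit_ad(Z_train, k_fraction = config$ad$k_fraction)
  pct_outside <- ad_coverage(ad, Z_test)
  pipeline_log(log_path, "ad", "k=%d, %.2f%% of test outside the AD",
               ad$k_neighbors, pct_outside)

  grid <- grid_spec(max_depth_values = config$grid$max_depth,
                    eta_values = config$grid$eta,
                    max_rounds = config$grid$max_rounds,
                    n_folds = config$grid$n_folds)
  X_train <- train$X
  X_test <- test$X
  selection <- NULL
  if (isTRUE(config$selection$enabled)) {
    selection <- fsti_select(X_train, train$y, m = config$selection$m,
                             corr_threshold = config$selection$corr_threshold,
                             inner_folds = config$selection$folds,
                             seed = seed, grid = grid)
    X_train <- X_train[, selection$selected_names, drop = FALSE]
    X_test <- X_test[, selection$selected_names, drop = FALSE]
    pipeline_log(log_path, "fsti", "selected %d of %d descriptors",
                 length(selection$selected_names), length(selection$ranked_names))
  }
  spec <- grid_search_cv(X_train, train$y, grid = grid, seed = seed)
  pipeline_log(log_path, "tune", "max_depth=%d eta=%g nrounds=%d rmsecv=%.4f",
               spec$max_depth, spec$eta, spec$nrounds, attr(spec, "rmsecv"))
  metrics <- evaluate_model(spec, X_train, train$y, X_test, test$y,
                            n_folds = grid$n_folds)

  levels <- sort(as.numeric(config$conformal$levels), decreasing = TRUE)
  st <- conformal_state(X_train, train$y, X_test, spec,
                        n_folds = grid$n_folds,
                        n_repeats = config$conformal$n_repeats,
                        ids_test = test$ids,
                        Z_train = apply_preprocessor(prep, train)[, intersect(prep$kept_columns, colnames(X_train)), drop = FALSE],
                        Z_test = apply_preprocessor(prep, test)[, intersect(prep$kept_columns, colnames(X_train)), drop = FALSE])
  ar_iv <- conformal_intervals(st, "AR", levels = levels)
  configs <- list()
  for (nc in setdiff(config$conformal$nc_types, "AR")) {
    betas <- if (nc %in% c("RMSExT")) 0 else config$conformal$betas
    for (b in betas) {
      nm <- if (nc == "RMSExT") nc else sprintf("%s_beta%g", nc, b)
      configs[[nm]] <- conformal_intervals(st, nc, beta = b, levels = levels,
                                           k = config$conformal$knn_k)
    }
  }
  pipeline_log(log_path, "conformal", "%d configurations + AR baseline",
               length(configs))

  vreps <- lapply(c(list(AR = ar_iv), configs), validation_report,
                  y_true = test$y, alpha = config$validation$alpha)
  eff <- efficiency(configs, ar_iv)
  winner <- tryCatch(select_optimal_cp(eff, vreps[names(configs)]),
                     error = function(e) NULL)

  report <- list(
    seed = seed,
    n_train = length(train$ids), n_test = length(test$ids),
    ad_pct_outside = pct_outside,
    rmsecv = metrics$rmsecv, rmsev = metrics$rmsev,
    r2_cv = metrics$r2_cv, r2_v = metrics$r2_v,
    pct_logs_07_v = metrics$pct07_v, pct_logs_10_v = metrics$pct10_v,
    selected_descriptors = if (!is.null(selection)) selection$selected_names,
    tuned = list(max_depth = spec$max_depth, eta = spec$eta,
                 nrounds = spec$nrounds),
    levels = levels,
    validation = lapply(vreps, function(v) v[, c("level", "error_rate", "p_value", "passed")]),
    efficiency = as.data.frame(eff),
    winner = winner
  )

  any_valid <- !is.null(winner) && any(!is.na(winner$per_level))
  if (any_valid) {
    pick <- if (!is.na(winner$overall)) winner$overall else {
      stats::na.omit(winner$per_level)[1L]
    }
    best_iv <- if (pick == "AR") ar_iv else configs[[pick]]
    utils::write.csv(as.data.frame(best_iv),
                     file.path(config$out_dir, "intervals.csv"),
                     row.names = FALSE)
    if (all(c("90", "80", "70") %in% colnames(best_iv$halfwidth)) &&
        !best_iv$nc_type %in% c("AR", "RMSExT")) {
      classes <- classify_compounds(best_iv)
      utils::write.csv(classes, file.path(config$out_dir, "classes.csv"),
                       row.names = FALSE)
      prof <- accuracy_profile(best_iv, levels = intersect(levels, c(90, 80, 70)))
      report$class_fractions <- as.list(table(classes$accuracy_class) /
                                          nrow(classes))
      report$overall_accuracy <- prof$overall_accuracy
      jsonlite::write_json(
        list(levels = prof$levels, fractions = prof$fractions,
             band_accuracy = prof$band_accuracy,
             band_fraction = prof$band_fraction,
             overall_accuracy = prof$overall_accuracy),
        file.path(config$out_dir, "profile.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      pipeline_log(log_path, "classify", "overall accuracy estimate %.1f%%",
                   prof$overall_accuracy)
    }
    report$selected_config <- pick
  } else {
    pipeline_log(log_path, "classify",
                 "skipped: no configuration passed validation at any level")
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  pipeline_log(log_path, "done", "artifacts in %s", config$out_dir)
  out <- config$out_dir
  attr(out, "report") <- report
  invisible(out)
}

#' Human-readable summary of a completed run
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Character vector of summary lines (also printed).
#' @export
run_report <- function(run_dir) {
  path <- file.path(run_dir, "report.json")
  if (!file.exists(path)) {
    stopf("incomplete run: missing %s", path)
  }
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  lines <- c(
    sprintf("Run in %s (seed %d): %d train / %d test compounds",
            run_dir, rep$seed, rep$n_train, rep$n_test),
    sprintf("Accuracy model: RMSECV %.3f, RMSEV %.3f, R2(CV) %.3f, R2(V) %.3f",
            rep$rmsecv, rep$rmsev, rep$r2_cv, rep$r2_v),
    sprintf("%%LogS+/-0.7 (V) %.1f%%, %%LogS+/-1.0 (V) %.1f%%",
            rep$pct_logs_07_v, rep$pct_logs_10_v),
    sprintf("AD: %.2f%% of test compounds outside", rep$ad_pct_outside)
  )
  for (nm in names(rep$validation)) {
    v <- rep$validation[[nm]]
    lines <- c(lines, sprintf(
      "  %s: error rates %s", nm,
      paste(sprintf("%g%%:%.3f%s", v$level, v$error_rate,
                    ifelse(v$passed, "", "*")), collapse = " ")))
  }
  if (!is.null(rep$selected_config)) {
    lines <- c(lines, sprintf("Selected configuration: %s", rep$selected_config))
  }
  if (!is.null(rep$overall_accuracy)) {
    lines <- c(lines, sprintf("Overall %%LogS+/-1 accuracy estimate: %.1f%%",
                              rep$overall_accuracy))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
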