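#' Descriptor table container
#'
#' Holds compound identifiers, an optional SMILES column, a numeric descriptor
#' matrix with named columns, and an optional experimental Log(S) target
#' (log10 mol/L). Row order is meaningful: the sequential train/test splits
#' operate on it.
#'
#' @param ids character vector of unique compound identifiers.
#' @param X numeric matrix, one row per compound, uniquely named columns.
#' @param y optional numeric target vector (may contain NA).
#' @param smiles optional character vector of SMILES strings.
#' @return An object of class `descriptor_table` (list with `ids`, `smiles`,
#'   `X`, `y`).
#' @export
descriptor_table <- function(ids, X, y = NULL, smiles = NULL) {
  ids <- as.character(ids)
  if (!is.matrix(X) || !is.numeric(X)) stopf("X must be a numeric matrix")
  if (is.null(colnames(X)) || anyDuplicated(colnames(X))) {
    stopf("X must have unique column names")
  }
  n <- length(ids)
  if (nrow(X) != n) stopf("ids and X disagree on row count (%d vs %d)", n, nrow(X))
  if (anyDuplicated(ids)) {
    stopf("duplicate compound id: %s", ids[duplicated(ids)][1L])
  }
  if (!is.null(y) && length(y) != n) stopf("y must have one value per compound")
  if (!is.null(smiles) && length(smiles) != n) {
    stopf("smiles must have one value per compound")
  }
  structure(
    list(ids = ids, smiles = smiles, X = X, y = if (!is.null(y)) as.numeric(y)),
    class = "descriptor_table"
  )
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat(sprintf(
    "<descriptor_table> %d compounds x %d descriptors%s%s\n",
    length(x$ids), ncol(x$X),
    if (!is.null(x$y)) ", with Log(S)" else "",
    if (!is.null(x$smiles)) ", with SMILES" else ""
  ))
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$X)

#' Read a descriptor table from CSV
#'
#' Parses a CSV with one row per compound. Empty cells and the markers
#' `NA`/`NaN` become missing values; `Inf`/`-Inf` parse as infinities (both
#' are later dropped by [fit_preprocessor()]). Row order is preserved.
#'
#' @param path CSV file path.
#' @param id_column name of the identifier column (default `"compound_id"`).
#' @param target_column optional name of the Log(S) column.
#' @param smiles_column optional name of a SMILES column.
#' @return A [descriptor_table()].
#' @export
read_descriptor_table <- function(path, id_column = "compound_id",
                                  target_column = NULL, smiles_column = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("", "NA", "NaN"), colClasses = "character")
  if (!id_column %in% names(df)) stopf("id column '%s' not present in %s", id_column, path)
  ids <- df[[id_column]]
  if (anyDuplicated(ids)) {
    stopf("duplicate compound id in %s: %s", path, ids[duplicated(ids)][1L])
  }
  smiles <- if (!is.null(smiles_column)) {
    if (!smiles_column %in% names(df)) stopf("SMILES column '%s' not present", smiles_column)
    df[[smiles_column]]
  }
  y <- NULL
  desc_cols <- setdiff(names(df), c(id_column, smiles_column, target_column))
  parse_num <- function(col, nm) {
    out <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(out) & !is.na(col))
    if (length(bad)) {
      stopf("non-numeric value '%s' in column '%s', row %d", col[bad[1L]], nm, bad[1L])
    }
    out
  }
  if (!is.null(target_column)) {
    if (!target_column %in% names(df)) stopf("target column '%s' not present", target_column)
    y <- parse_num(df[[target_column]], target_column)
  }
  X <- vapply(desc_cols, function(nm) parse_num(df[[nm]], nm), numeric(nrow(df)))
  if (nrow(df) == 1L) X <- matrix(X, nrow = 1L, dimnames = list(NULL, desc_cols))
  descriptor_table(ids = ids, X = X, y = y, smiles = smiles)
}

#' Write a descriptor table to CSV
#'
#' Inverse of [read_descriptor_table()]; columns are `compound_id`, optional
#' `smiles`, the descriptors, and optional `logS`.
#'
#' @param table a [descriptor_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  stopifnot(inherits(table, "descriptor_table"))
  df <- data.frame(compound_id = table$ids, stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!is.null(table$smiles)) df$smiles <- table$smiles
  df <- cbind(df, as.data.frame(table$X, check.names = FALSE))
  if (!is.null(table$y)) df$logS <- table$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a SMILES list (.smi)
#'
#' One SMILES per line, optionally followed by a whitespace-separated
#' identifier. Bookkeeping only; no chemistry is performed.
#'
#' @param path .smi file path.
#' @return data.frame with columns `smiles` and `id` (NA when absent).
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1L),
    id = vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE
  )
}

#' Fit training-set preprocessing (column filtering, centring, scaling)
#'
#' Drops every descriptor column that, on the training rows, contains a
#' missing or non-finite value or has a single unique value; records the
#' training mean and sample standard deviation (n-1 denominator) of each kept
#' column. Test and query data must be transformed with the training model:
#' no statistic of any other set ever enters it.
#'
#' @param train a [descriptor_table()] with at least 2 rows.
#' @return An object of class `preprocess_model` with `kept_columns`, `means`,
#'   `scales`.
#' @export
fit_preprocessor <- function(train) {
  stopifnot(inherits(train, "descriptor_table"))
  X <- train$X
  if (nrow(X) < 2L) stopf("need at least 2 training rows")
  keep <- vapply(seq_len(ncol(X)), function(j) {
    col <- X[, j]
    all(is.finite(col)) && length(unique(col)) > 1L
  }, logical(1))
  if (!any(keep)) stopf("all descriptor columns removed by preprocessing")
  kept <- colnames(X)[keep]
  Xk <- X[, keep, drop = FALSE]
  structure(
    list(
      kept_columns = kept,
      means = colMeans(Xk),
      scales = apply(Xk, 2L, stats::sd)
    ),
    class = "preprocess_model"
  )
}

#' Apply a fitted preprocessing model
#'
#' Returns `(x - mean) / scale` for every kept column, using the training
#' statistics stored in `model`. Applying a model to its own training table
#' yields column means 0 and SDs 1; shifted test data keep their shift.
#'
#' @param model a [fit_preprocessor()] result.
#' @param table a [descriptor_table()] or numeric matrix containing all kept
#'   columns.
#' @return Scaled numeric matrix over `model$kept_columns`.
#' @export
apply_preprocessor <- function(model, table) {
  stopifnot(inherits(model, "preprocess_model"))
  X <- if (inherits(table, "descriptor_table")) table$X else table
  missing_cols <- setdiff(model$kept_columns, colnames(X))
  if (length(missing_cols)) {
    stopf("columns missing from data: %s", paste(missing_cols, collapse = ", "))
  }
  X <- X[, model$kept_columns, drop = FALSE]
  scale(X, center = model$means, scale = model$scales)[, , drop = FALSE]
}

#' Sequential train/test split rule
#'
#' Every `period`-th row, starting at each 1-based `offset`, goes to the test
#' side. An optional `nested` rule is applied to the positions of the
#' already-built test subset and moves its matching members back to training
#' (used for "middle set" constructions).
#'
#' @param period cycle length (>= 2).
#' @param offsets integer vector of 1-based start offsets in `1..period`.
#' @param nested optional `split_rule` applied within the test subset.
#' @return An object of class `split_rule`.
#' @export
split_rule <- function(period, offsets, nested = NULL) {
  if (!is_count(period) || period < 2) stopf("period must be an integer >= 2")
  if (!length(offsets) || !all(vapply(offsets, is_count, logical(1)))) {
    stopf("offsets must be positive integers")
  }
  offsets <- as.integer(offsets)
  if (any(offsets > period)) stopf("offsets must lie in 1..period")
  if (!is.null(nested) && !inherits(nested, "split_rule")) {
    stopf("nested must be a split_rule")
  }
  structure(list(period = as.integer(period), offsets = offsets, nested = nested),
            class = "split_rule")
}

seq_positions <- function(n, period, offsets) {
  idx <- seq_len(n)
  hit <- rep(FALSE, n)
  for (o in offsets) hit <- hit | ((idx - o) %% period == 0)
  idx[hit]
}

#' Perform a sequential train/test split
#'
#' Deterministic positional split: row `i` (1-based) is a test row iff
#' `i = offset (mod period)` for some offset of the rule. Nested rules then
#' move designated members of the test subset (by their 1-based position
#' within that subset) back to the training side.
#'
#' @param table a [descriptor_table()] (or anything with rows; only the row
#'   count is used).
#' @param rule a [split_rule()].
#' @return List with 1-based integer vectors `train_idx` and `test_idx`
#'   partitioning the rows.
#' @examples
#' tab <- generate_dataset(synth_spec(12, seed = 1))
#' sequential_split(tab, split_rule(6, 2))$test_idx  # 2, 8
#' @export
sequential_split <- function(table, rule) {
  stopifnot(inherits(rule, "split_rule"))
  n <- if (inherits(table, "descriptor_table")) length(table$ids)
       else if (is.matrix(table) || is.data.frame(table)) nrow(table)
       else as.integer(table)
  if (is.na(n) || n < 1L) stopf("table must be non-empty")
  test <- seq_positions(n, rule$period, rule$offsets)
  if (!is.null(rule$nested)) {
    back <- seq_positions(length(test), rule$nested$period, rule$nested$offsets)
    # nested matches leave the subset and return to training
    test <- test[-back]
  }
  train <- setdiff(seq_len(n), test)
  if (!length(test) || !length(train)) {
    stopf("degenerate split: train has %d rows, test has %d rows",
          length(train), length(test))
  }
  list(train_idx = train, test_idx = test)
}

#' Subset a descriptor table by row indices
#'
#' @param table a [descriptor_table()].
#' @param idx integer row indices.
#' @return A [descriptor_table()] with the selected rows.
#' @export
subset_table <- function(table, idx) {
  stopifnot(inherits(table, "descriptor_table"))
  descriptor_table(
    ids = table$ids[idx],
    X = table$X[idx, , drop = FALSE],
    y = if (!is.null(table$y)) table$y[idx],
    smiles = if (!is.null(table$smiles)) table$smiles[idx]
  )
}
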