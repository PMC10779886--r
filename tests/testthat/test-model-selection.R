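make_regression <- function(n, p_noise, seed, effects = c(2, 1.5, 1)) {
  tab <- generate_dataset(synth_spec(
    n, n_informative = length(effects), n_noise = p_noise,
    effect_sizes = effects, noise_base = 0.3, noise_slope = 0, seed = seed
  ))
  list(X = tab$X, y = tab$y)
}

test_that("a single-point grid returns that point", {
  d <- make_regression(80, 4, 1)
  spec <- grid_search_cv(d$X, d$y, small_grid(), seed = 1)
  expect_equal(spec$max_depth, 2L)
  expect_equal(spec$eta, 0.3)
  expect_true(spec$nrounds >= 1)
  expect_length(spec$folds, 80)
})

test_that("the grid winner matches a brute-force re-evaluation", {
  d <- make_regression(90, 3, 2)
  grid <- grid_spec(max_depth_values = c(1, 3), eta_values = c(0.2, 0.6),
                    max_rounds = 20, n_folds = 5)
  spec <- grid_search_cv(d$X, d$y, grid, seed = 7)
  # oracle: manual per-fold training with per-iteration predictions,
  # averaging the per-fold RMSE curves, independent of the CV driver used
  # inside the package
  folds <- spec$folds
  oracle_rmsecv <- function(depth, eta) {
    curves <- sapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      m <- fit_learner(learner_spec(depth, eta, nrounds = 20), d$X[tr, ], d$y[tr])
      sapply(1:20, function(i) {
        p <- predict(m, xgboost::xgb.DMatrix(d$X[!tr, , drop = FALSE], nthread = 1),
                     iterationrange = c(1, i))
        sqrt(mean((d$y[!tr] - p)^2))
      })
    })
    min(rowMeans(curves))
  }
  pts <- expand.grid(depth = c(1, 3), eta = c(0.2, 0.6))
  scores <- mapply(oracle_rmsecv, pts$depth, pts$eta)
  best <- pts[which.min(scores), ]
  expect_equal(spec$max_depth, best$depth)
  expect_equal(spec$eta, best$eta)
  expect_equal(attr(spec, "rmsecv"), min(scores), tolerance = 1e-6)
})

test_that("the fine grid uses 60 equidistant eta values in (0, 0.4]", {
  g <- grid_spec(fine_grid = TRUE)
  expect_length(g$eta_values, 60L)
  expect_equal(max(g$eta_values), 0.4)
  expect_true(all(diff(g$eta_values) > 0))
  expect_equal(sd(diff(g$eta_values)), 0, tolerance = 1e-12)
})

test_that("importance ranking puts a planted strong feature on top", {
  d <- make_regression(60, 0, 3, effects = 2)
  spec <- small_learner()
  m <- fit_learner(spec, d$X[, 1, drop = FALSE], d$y)
  expect_equal(importance_ranking(m)$name[1], "sig_01")

  hits <- 0L
  for (s in 1:20) {
    dd <- make_regression(250, 10, 100 + s, effects = 3)
    m <- fit_learner(small_learner(), dd$X, dd$y)
    rk <- importance_ranking(m)$name
    if ("sig_01" %in% rk[1:3]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("zero-importance features are appended in original column order", {
  d <- make_regression(60, 6, 4, effects = 5)
  m <- fit_learner(small_learner(nrounds = 10), d$X, d$y)
  rk <- importance_ranking(m)
  zero <- rk$name[rk$gain == 0]
  expect_identical(zero, intersect(colnames(d$X), zero))
  expect_setequal(rk$name, colnames(d$X))
})

test_that("FSTI recovers planted features and keeps the RMSECV minimum contract", {
  recovered <- 0L
  for (s in 1:3) {
    d <- make_regression(250, 12, 200 + s, effects = c(2, 1.5, 1))
    sel <- fsti_select(d$X, d$y, m = 6, inner_folds = 5, seed = s,
                       grid = small_grid(), inner_grid = "fixed")
    expect_true(all(sel$selected_names %in% sel$ranked_names))
    expect_gte(length(sel$selected_names), 3L)
    expect_equal(unname(sel$rmsecv_path[sel$stop_index]), min(sel$rmsecv_path))
    # selected names are a prefix of the usable ranking
    expect_identical(sel$selected_names,
                     sel$usable_names[seq_along(sel$selected_names)])
    if (all(c("sig_01", "sig_02", "sig_03") %in% sel$selected_names)) {
      recovered <- recovered + 1L
    }
  }
  expect_gte(recovered, 2L)
})

test_that("FSTI is reproducible under a fixed seed", {
  d <- make_regression(150, 8, 5)
  a <- fsti_select(d$X, d$y, m = 4, inner_folds = 4, seed = 3,
                   grid = small_grid(4), inner_grid = "fixed")
  b <- fsti_select(d$X, d$y, m = 4, inner_folds = 4, seed = 3,
                   grid = small_grid(4), inner_grid = "fixed")
  expect_identical(a$selected_names, b$selected_names)
  expect_identical(a$rmsecv_path, b$rmsecv_path)
})

test_that("the 0.9 correlation filter removes a duplicated descriptor", {
  d <- make_regression(120, 5, 6)
  set.seed(42)
  X <- cbind(d$X, dup_sig = d$X[, "sig_01"] + rnorm(120, sd = 1e-6))
  sel <- fsti_select(X, d$y, m = 4, inner_folds = 4, seed = 2,
                     corr_threshold = 0.9, grid = small_grid(4),
                     inner_grid = "fixed")
  expect_false(all(c("sig_01", "dup_sig") %in% sel$usable_names))
  expect_false("dup_sig" %in% sel$selected_names && "sig_01" %in% sel$selected_names)
})

test_that("degenerate selection inputs error", {
  d <- make_regression(50, 2, 7)
  expect_error(fsti_select(d$X, d$y, m = 2, grid = small_grid(4)), "m must")
})

test_that("accuracy metrics count residuals inclusively and match closed forms", {
  expect_equal(pct_within(c(0.5, 0.8, 1.2), 0.7), 100 / 3)
  expect_equal(pct_within(c(0.5, 0.8, 1.2), 1.0), 200 / 3)
  expect_equal(pct_within(c(0.7, -0.7), 0.7), 100)  # boundary is within

  d <- make_regression(100, 3, 8)
  spec <- grid_search_cv(d$X[1:80, ], d$y[1:80], small_grid(), seed = 1)
  m <- evaluate_model(spec, d$X[1:80, ], d$y[1:80], d$X[81:100, ], d$y[81:100],
                      n_folds = 5)
  expect_equal(m$rmsev, sqrt(mean((d$y[81:100] - m$test_pred)^2)))
  expect_equal(m$rmsecv, sqrt(mean((d$y[1:80] - m$cv_pred)^2)))
  expect_equal(m$pct10_v, pct_within(d$y[81:100] - m$test_pred, 1.0))
  # perfect predictions give the degenerate extremes
  expect_equal(pct_within(rep(0, 5), 0.7), 100)
})
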