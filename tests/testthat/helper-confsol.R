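# Shared fixtures, built in code.

# A small deterministic descriptor table with known quirks for I/O and
# preprocessing tests.
quirky_table <- function() {
  X <- cbind(
    good = c(1, 2, 3, 4),
    constant = c(7, 7, 7, 7),
    with_na = c(1, NA, 3, 4),
    with_inf = c(1, 2, Inf, 4),
    other = c(0.5, -0.5, 1.5, -1.5)
  )
  descriptor_table(ids = paste0("c", 1:4), X = X, y = c(-1, 0, 1, 2))
}

# Small learner used throughout the unit tests.
small_learner <- function(seed = 1L, nrounds = 30L) {
  learner_spec(max_depth = 2, eta = 0.3, nrounds = nrounds, seed = seed)
}

small_grid <- function(n_folds = 5L, max_rounds = 40L) {
  grid_spec(max_depth_values = 2, eta_values = 0.3, max_rounds = max_rounds,
            n_folds = n_folds)
}

# A small conformal state on synthetic heteroscedastic data, cached per
# session because several test files inspect it.
.state_cache <- new.env(parent = emptyenv())
small_state <- function() {
  if (is.null(.state_cache$st)) {
    tab <- generate_dataset(synth_spec(150, n_noise = 10, seed = 11))
    sp <- sequential_split(tab, split_rule(3, 2))
    spec <- small_learner(seed = 11)
    .state_cache$tab <- tab
    .state_cache$sp <- sp
    .state_cache$st <- conformal_state(
      tab$X[sp$train_idx, ], tab$y[sp$train_idx], tab$X[sp$test_idx, ], spec,
      n_folds = 5, n_repeats = 4, ids_test = tab$ids[sp$test_idx]
    )
    .state_cache$y_test <- tab$y[sp$test_idx]
  }
  .state_cache
}

# Calibration records crafted so that the ARSS 90% referent is exactly 2.0
# with median sigma 0.2 (see test-conformal.R interval arithmetic).
crafted_records <- function() {
  alphas <- c(seq(0.2, 1.6, by = 0.2), 2.0, 2.5)
  data.frame(
    id = sprintf("r%02d", seq_along(alphas)),
    y = 0.3 * alphas,
    y_hat_single = 0,
    mu_hat = 0,
    s = rep(0.2, length(alphas))
  )
}
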