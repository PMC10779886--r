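test_that("repeated CV aggregates match direct recomputation", {
  cache <- small_state()
  cvp <- cache$st$cvp
  expect_equal(cvp$mu, rowMeans(cvp$pred))
  expect_equal(cvp$s, apply(cvp$pred, 1, sd))
  expect_equal(cvp$first, cvp$pred[, 1])
  expect_equal(dim(cvp$pred), c(100L, 4L))
})

test_that("identical folds across repeats give zero prediction spread", {
  tab <- generate_dataset(synth_spec(24, n_noise = 2, seed = 4))
  spec <- small_learner(nrounds = 10)
  # leave-one-out folds are the same partition in every repeat
  cvp <- repeated_cv_predictions(tab$X, tab$y, spec, n_folds = 24, n_repeats = 2)
  expect_equal(max(cvp$s), 0)
})

test_that("sigma_test is the fold-model SD and ignores test labels", {
  cache <- small_state()
  st <- cache$st
  preds <- sapply(st$cvp$fold_models, function(m) predict_learner(m, st$X_test))
  expect_equal(st$sd_test, apply(preds, 1, sd))
  # constant training labels make every fold model constant
  tab <- generate_dataset(synth_spec(30, n_noise = 2, seed = 5))
  yc <- rep(2.5, 30)
  cvp <- repeated_cv_predictions(tab$X, yc, small_learner(nrounds = 5),
                                 n_folds = 5, n_repeats = 2)
  expect_equal(max(sigma_test(cvp$fold_models, tab$X[1:5, ])), 0,
               tolerance = 1e-10)
})

test_that("nonconformity scores follow their defining arithmetic", {
  rec <- data.frame(id = "a", y = 1.0, y_hat_single = 0.5, mu_hat = 0.6, s = 0.5)
  p_arss <- nc_scores(rec, "ARSS", beta = 0)
  expect_equal(max(p_arss$scores), 0.5 / 0.5)  # |y - y1| / s
  p_ars <- nc_scores(rec, "ARS", beta = 0)
  expect_equal(max(p_ars$scores), abs(1.0 - 0.6) / 0.5)  # |y - mu| / s
  # AR with residuals 0.1..1.0: nearest-rank 80th percentile is 0.8
  rec10 <- data.frame(id = paste0("r", 1:10), y = (1:10) / 10,
                      y_hat_single = 0, mu_hat = 0, s = 1)
  p_ar <- nc_scores(rec10, "AR")
  expect_equal(unname(p_ar$referents["80"]), 0.8)
  expect_equal(unname(p_ar$referents["90"]), 0.9)
  expect_equal(unname(p_ar$referents["99"]), 1.0)
  expect_equal(p_ar$scores, sort((1:10) / 10, decreasing = TRUE))
})

test_that("degenerate normalization names the offending compounds", {
  rec <- data.frame(id = c("ok", "flat"), y = c(1, 2),
                    y_hat_single = c(0.5, 1), mu_hat = c(0.5, 1), s = c(0.3, 0))
  expect_error(nc_scores(rec, "ARSS", beta = 0), "flat")
  # raising beta resolves it
  expect_s3_class(nc_scores(rec, "ARSS", beta = 0.5), "nc_profile")
})

test_that("interval half-width arithmetic is exact", {
  prof <- nc_scores(crafted_records(), "ARSS", beta = 0.5)
  expect_equal(unname(prof$referents["90"]), 2.0)
  expect_equal(prof$med_sigma, 0.2)
  hw <- interval_halfwidth(prof, sigma_test = 0.4, confidence = 90)
  expect_equal(hw, (0.5 * 0.2 + 0.4) * 2.0)  # = 1.0
  expect_error(interval_halfwidth(prof, 0.4, 85), "85")
})

test_that("the worked solubility example reproduces its printed intervals", {
  we <- worked_example()
  norm_iv <- build_intervals("1-pentanol", we$center,
                             matrix(we$halfwidths, ncol = 1,
                                    dimnames = list(NULL, "90")))
  expect_equal(unname(norm_iv$lower[1, "90"]), -1.222)
  expect_equal(unname(norm_iv$upper[1, "90"]), 0.382)
  ar_iv <- build_intervals("1-pentanol", we$center,
                           matrix(we$ar_halfwidths, ncol = 1,
                                  dimnames = list(NULL, "90")))
  expect_equal(unname(ar_iv$lower[1, "90"]), -1.649)
  expect_equal(unname(ar_iv$upper[1, "90"]), 0.809)
  # degenerate half-width collapses onto the centre
  z <- build_intervals("x", 1.5, matrix(0, ncol = 1, dimnames = list(NULL, "90")))
  expect_equal(unname(z$lower[1, "90"]), 1.5)
  expect_equal(unname(z$upper[1, "90"]), 1.5)
  expect_error(build_intervals("x", 0, matrix(-1, ncol = 1,
                                              dimnames = list(NULL, "90"))),
               "negative")
})

test_that("intervals are symmetric with level-monotone half-widths", {
  cache <- small_state()
  for (nc in c("ARSS", "ARS", "EM-N", "EM-Log")) {
    iv <- conformal_intervals(cache$st, nc, beta = 0.5)
    expect_equal(iv$upper - iv$center, iv$center - iv$lower, tolerance = 1e-12)
    hw <- iv$halfwidth
    expect_true(all(hw[, "99"] >= hw[, "95"] & hw[, "95"] >= hw[, "90"] &
                      hw[, "90"] >= hw[, "80"]))
  }
})

test_that("AR and RMSExT intervals are constant across compounds", {
  cache <- small_state()
  ar <- conformal_intervals(cache$st, "AR")
  expect_equal(sd(ar$halfwidth[, "90"]), 0)
  rt <- conformal_intervals(cache$st, "RMSExT")
  expect_equal(sd(rt$halfwidth[, "95"]), 0)
  # RMSExT half-width is t-quantile times RMSECV
  n_train <- nrow(cache$st$X_train)
  expect_equal(unname(rt$halfwidth[1, "95"]),
               qt(0.975, n_train - 1) * cache$st$rmsecv)
})

test_that("large beta drives normalized widths to a common constant", {
  cache <- small_state()
  cv_of <- function(beta) {
    hw <- conformal_intervals(cache$st, "ARSS", beta = beta)$halfwidth[, "90"]
    sd(hw) / mean(hw)
  }
  expect_lt(cv_of(100), 0.01)
  expect_lt(cv_of(100), cv_of(0.2))
})

test_that("error-model difficulty tracks the true noise scale", {
  tab <- generate_dataset(synth_spec(300, n_noise = 10, seed = 21))
  sp <- sequential_split(tab, split_rule(3, 2))
  spec <- small_learner(seed = 21)
  st <- conformal_state(tab$X[sp$train_idx, ], tab$y[sp$train_idx],
                        tab$X[sp$test_idx, ], spec, n_folds = 10, n_repeats = 5)
  prof <- nc_em(st, "normal", beta = 0.2)
  truth <- 0.2 + 0.6 * tab$X[sp$train_idx, 1]
  ct <- cor.test(prof$sigma_cal, truth, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
  # the log variant returns strictly positive difficulty
  prof_log <- nc_em(st, "log", beta = 0.2)
  expect_true(all(prof_log$sigma_cal > 0))
  expect_true(all(prof_log$sigma_test > 0))
})

test_that("EM-N intervals are near the AR baseline on homoscedastic data", {
  tab <- generate_dataset(synth_spec(420, n_noise = 10, noise_base = 0.5,
                                     noise_slope = 0, seed = 22))
  sp <- sequential_split(tab, split_rule(3, 2))
  st <- conformal_state(tab$X[sp$train_idx, ], tab$y[sp$train_idx],
                        tab$X[sp$test_idx, ], small_learner(seed = 22),
                        n_folds = 10, n_repeats = 8)
  em <- conformal_intervals(st, "EM-N", beta = 1)
  ar <- conformal_intervals(st, "AR")
  ratio <- median(em$halfwidth[, "90"]) / median(ar$halfwidth[, "90"])
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("kNN difficulty matches brute-force mean distances", {
  tab <- generate_dataset(synth_spec(20, n_noise = 2, seed = 23))
  Z <- apply_preprocessor(fit_preprocessor(tab), tab)
  spec <- small_learner(nrounds = 5, seed = 23)
  # leave-one-out folds: the fold-training portion is "all other samples" in
  # every repeat, so the CV-loop average equals the direct computation
  st <- conformal_state(tab$X, tab$y, tab$X[1:6, ], spec,
                        n_folds = 20, n_repeats = 2, Z_train = Z,
                        Z_test = Z[1:6, , drop = FALSE])
  prof <- nc_knn_eud(st, k = 3, beta = 0.2)
  oracle_cal <- vapply(1:20, function(i) {
    d <- sqrt(colSums((t(Z[-i, , drop = FALSE]) - Z[i, ])^2))
    mean(sort(d)[1:3])
  }, numeric(1))
  expect_equal(prof$sigma_cal, oracle_cal, tolerance = 1e-10)
  # test difficulty measures against the full training set: a coincident
  # query includes a zero distance
  oracle_test1 <- mean(sort(sqrt(colSums((t(Z) - Z[1, ])^2)))[1:3])
  expect_equal(prof$sigma_test[1], oracle_test1, tolerance = 1e-6)
  expect_equal(sort(sqrt(colSums((t(Z) - Z[1, ])^2)))[1], 0)
  expect_error(nc_knn_eud(st, k = 19), "fold-training")
})

test_that("a dense-cluster member gets smaller kNN sigma than an outlier", {
  set.seed(31)
  Z <- rbind(matrix(rnorm(30, sd = 0.1), 15, 2),
             c(5, 5))
  colnames(Z) <- c("a", "b")
  y <- rnorm(16)
  spec <- small_learner(nrounds = 5, seed = 31)
  st <- conformal_state(Z, y, Z[1:2, ], spec, n_folds = 4, n_repeats = 2,
                        Z_train = Z, Z_test = Z[1:2, , drop = FALSE])
  prof <- nc_knn_eud(st, k = 3, beta = 0.5)
  expect_lt(prof$sigma_cal[1], prof$sigma_cal[16])
})

test_that("the conformal pipeline is deterministic under a fixed seed", {
  tab <- generate_dataset(synth_spec(80, n_noise = 5, seed = 13))
  sp <- sequential_split(tab, split_rule(4, 2))
  run <- function() {
    st <- conformal_state(tab$X[sp$train_idx, ], tab$y[sp$train_idx],
                          tab$X[sp$test_idx, ], small_learner(seed = 13),
                          n_folds = 5, n_repeats = 3)
    as.data.frame(conformal_intervals(st, "ARSS", beta = 0.3))
  }
  expect_identical(run(), run())
})

test_that("empirical coverage at 90% is plausible on held-out data", {
  cache <- small_state()
  iv <- conformal_intervals(cache$st, "ARSS", beta = 0.5)
  er <- error_rate(iv, cache$y_test)
  expect_lt(er[["90"]], 0.30)
  expect_gte(er[["99"]], 0)
})
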