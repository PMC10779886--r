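interval_fixture <- function(centers, hw_by_level) {
  hw <- sapply(names(hw_by_level), function(lv) rep(hw_by_level[[lv]],
                                                    length(centers)))
  if (is.null(dim(hw))) hw <- matrix(hw, nrow = 1)
  colnames(hw) <- names(hw_by_level)
  build_intervals(sprintf("c%03d", seq_along(centers)), centers, hw,
                  nc_type = "fixture")
}

test_that("error rates count strict exceedances only", {
  iv <- interval_fixture(rep(0, 4), list("90" = 1))
  # y on the centre, inside, on the bound, outside
  er <- error_rate(iv, c(0, 0.5, 1.0, 1.5))
  expect_equal(unname(er["90"]), 0.25)
  expect_equal(unname(error_rate(iv, rep(0, 4))["90"]), 0)
  expect_error(error_rate(iv, 1:3), "4 compounds")
})

test_that("5 misses out of 36 is 13.89% and passes the 90% validation", {
  flags <- c(rep(1, 5), rep(0, 31))
  expect_equal(mean(flags) * 100, 13.89, tolerance = 1e-3)
  v <- validate_error_rate(flags, 0.90)
  expect_true(v$passed)
  expect_gte(v$p_value, 0.01)
})

test_that("a grossly inflated error rate fails validation", {
  flags <- c(rep(1, 300), rep(0, 700))
  v <- validate_error_rate(flags, 0.99)
  expect_false(v$passed)
  expect_lt(v$p_value, 1e-10)
  # and the exactly-expected vector gives p = 1
  n <- 50
  exact <- c(rep(1, 5), rep(0, 45))
  expect_equal(validate_error_rate(exact, 0.90)$p_value, 1)
  expect_error(validate_error_rate(exact, 1.5), "confidence")
})

test_that("validation reports cover every level of the interval set", {
  cache <- small_state()
  iv <- conformal_intervals(cache$st, "ARSS", beta = 0.5)
  vr <- validation_report(iv, cache$y_test)
  expect_equal(vr$level, c(99, 95, 90, 80))
  expect_true(all(vr$error_rate >= 0 & vr$error_rate <= 1))
  expect_identical(vr$passed, vr$p_value >= 0.01)
})

test_that("efficiency gain follows Q2(AR)/Q2(CP) - 1", {
  ar <- interval_fixture(rep(0, 10), list("90" = 1.2))
  cp <- interval_fixture(rep(0, 10), list("90" = 1.0))
  eff <- efficiency(list(cp = cp), ar)
  expect_equal(eff$gain_vs_ar, 0.2)
  expect_equal(eff$median_hw, 1.0)
  # identical configurations: zero gain, non-significant test
  eff0 <- efficiency(list(same = ar), ar)
  expect_equal(eff0$gain_vs_ar, 0)
  expect_gte(eff0$p_value_vs_ar, 0.01)
})

test_that("optimal configuration selection scans levels independently", {
  mk <- function(h80, h90) interval_fixture(rep(0, 6),
                                            list("90" = h90, "80" = h80))
  ar <- mk(2, 2.4)
  eff <- efficiency(list(A = mk(0.8, 2.0), B = mk(1.5, 1.0)), ar)
  pass_all <- data.frame(level = c(90, 80), passed = c(TRUE, TRUE))
  win <- select_optimal_cp(eff, list(A = pass_all, B = pass_all))
  expect_equal(unname(win$per_level["80"]), "A")
  expect_equal(unname(win$per_level["90"]), "B")
  # the overall winner minimizes the mean of all per-level statistics
  avg <- function(cfg) mean(eff$mean_hw[eff$config == cfg]) / 2 +
    mean(eff$median_hw[eff$config == cfg]) / 2
  expect_equal(win$overall, c("A", "B")[which.min(c(avg("A"), avg("B")))])
  # order invariance
  eff_rev <- efficiency(list(B = mk(1.5, 1.0), A = mk(0.8, 2.0)), ar)
  win_rev <- select_optimal_cp(eff_rev, list(B = pass_all, A = pass_all))
  expect_identical(win$per_level, win_rev$per_level)
  expect_identical(win$overall, win_rev$overall)
})

test_that("configurations failing validation are ineligible", {
  mk <- function(h80, h90) interval_fixture(rep(0, 6),
                                            list("90" = h90, "80" = h80))
  ar <- mk(2, 2.4)
  eff <- efficiency(list(A = mk(0.8, 2.0), B = mk(1.5, 1.0)), ar)
  fail90 <- data.frame(level = c(90, 80), passed = c(FALSE, TRUE))
  pass_all <- data.frame(level = c(90, 80), passed = c(TRUE, TRUE))
  win <- select_optimal_cp(eff, list(A = pass_all, B = fail90))
  expect_equal(unname(win$per_level["90"]), "A")  # B is out at 90%
  expect_equal(win$overall, "A")
  fail_all <- data.frame(level = c(90, 80), passed = c(FALSE, FALSE))
  expect_error(select_optimal_cp(eff, list(A = fail_all, B = fail_all)),
               "no configuration")
})

test_that("half-width/residual correlation is exact in the linear case", {
  set.seed(7)
  resid <- abs(rnorm(40))
  iv <- build_intervals(sprintf("c%02d", 1:40), rep(0, 40),
                        matrix(3 * resid, ncol = 1,
                               dimnames = list(NULL, "90")))
  out <- residual_interval_correlation(iv, resid, level = 90)
  expect_equal(out$r, 1, tolerance = 1e-12)
  expect_equal(out$r2, 1, tolerance = 1e-12)
  expect_lt(out$p_value, 1e-10)
  # constant-width intervals have no per-compound information
  ar <- interval_fixture(rep(0, 40), list("90" = 1.2))
  expect_error(residual_interval_correlation(ar, resid), "constant")
})

test_that("error rates are non-increasing in confidence for nested intervals", {
  cache <- small_state()
  iv <- conformal_intervals(cache$st, "ARSS", beta = 0.3)
  er <- error_rate(iv, cache$y_test)
  expect_true(all(diff(er[c("99", "95", "90", "80")]) >= 0))
})
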