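test_that("correlation reduction collapses duplicate and sign-flipped columns", {
  set.seed(1)
  x <- rnorm(40)
  d <- tibble::tibble(a = x, b = x, c = -x)
  r <- reduce_by_correlation(d, threshold = 0.9)
  expect_length(r$retained, 1)

  # 5 columns: two planted duplicate pairs + 1 independent -> 3 retained
  y <- rnorm(40); z <- rnorm(40); w <- rnorm(40)
  d5 <- tibble::tibble(f1 = y, f2 = y + rnorm(40, sd = 1e-6),
                       f3 = z, f4 = -z, f5 = w)
  r5 <- reduce_by_correlation(d5, threshold = 0.9)
  expect_length(r5$retained, 3)
  expect_true("f5" %in% r5$retained)
})

test_that("constant feature columns are dropped with a warning", {
  d <- tibble::tibble(a = rnorm(20), b = rep(2, 20))
  expect_warning(r <- reduce_by_correlation(d), "constant")
  expect_identical(r$retained, "a")
})

test_that("LASSO guards: single-class labels and n < k error", {
  d <- simulate_feature_cohort(10, 5, seed = 1)
  expect_error(fit_lasso_cv(d[3:7], rep("AS", 20)), "single class")
  expect_error(fit_lasso_cv(d[1:9, 3:7], d$class[c(1:5, 11:14)], k = 10),
               "folds")
})

test_that("LASSO recovers a planted signal with correct sign", {
  d <- simulate_feature_cohort(150, 50, n_informative = 2, effect = 1.5,
                               seed = 2)
  sc <- fit_lasso_cv(d, d$class, k = 10, seed = 3)
  expect_true(all(c("feat_001", "feat_002") %in% sc$features))
  expect_true(all(sc$weights[match(c("feat_001", "feat_002"),
                                   sc$features)] > 0))
})

test_that("scoring is the standardized weighted sum plus intercept", {
  sc <- structure(list(features = "f", weights = 2, intercept = 0,
                       center = 0, scale = 1, lambda = 0.1, k = 10, seed = 1,
                       positive = "AS", n_candidates = 1),
                  class = "linear_scorer")
  expect_equal(score_ril(tibble::tibble(f = 1.5), sc), 3.0)
  sc$weights <- 0
  sc$intercept <- -0.7
  expect_equal(score_ril(tibble::tibble(f = 99), sc), -0.7)
  sc$features <- "missing_col"
  sc$weights <- 1
  expect_error(score_ril(tibble::tibble(f = 1), sc), "missing_col")
})

test_that("scorer round-trips on its own training table", {
  d <- simulate_feature_cohort(40, 10, n_informative = 2, effect = 2, seed = 5)
  sc <- fit_lasso_cv(d, d$class, k = 5, seed = 6)
  s1 <- score_ril(d, sc)
  s2 <- score_ril(d, sc)
  expect_identical(s1, s2)
  expect_equal(predict(sc, d), s1)
  expect_true(all(is.finite(s1)))
  # selected-feature table and glance are consistent
  expect_equal(nrow(tidy(sc)), length(sc$features) + 1)
  expect_equal(glance(sc)$n_selected, length(sc$features))
})

test_that("Youden cutoff: worked example, midpoint rule, ties", {
  yd <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), positive = 1)
  expect_equal(yd$threshold, 0.5)
  expect_equal(yd$j, 1)
  # all scores equal: single candidate, J = 0
  yd0 <- youden_threshold(rep(0.3, 6), c(0, 0, 0, 1, 1, 1), positive = 1)
  expect_equal(yd0$threshold, 0.3)
  expect_equal(yd0$j, 0)
})

test_that("Youden J matches exhaustive search on random instances", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(6:30, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(rnorm(n), sample(0:2, 1))  # rounding forces ties
    yd <- youden_threshold(s, y, positive = 1)
    expect_equal(yd$j, oracle_youden_j(s, y), tolerance = 1e-9)
  }
})

test_that("RIS merging: worked examples including the tie branch", {
  expect_equal(merge_ris(0.42, 0.5), 0.42)            # single lesion
  expect_equal(merge_ris(c(0.2, 0.8, 0.9), 0.5), 0.85)
  expect_equal(merge_ris(c(0.4, 0.6), 0.5), 0.6)      # tie -> positive court
  expect_error(merge_ris(numeric(0), 0.5), "at least one")
})

test_that("RIS equals the literal piecewise expression on 1000 random draws", {
  set.seed(32)
  for (rep in 1:1000) {
    n <- sample(1:8, 1)
    rils <- round(rnorm(n), sample(1:3, 1))
    t <- round(rnorm(1), 1)
    expect_equal(merge_ris(rils, t), oracle_ris(rils, t), tolerance = 1e-12)
  }
})

test_that("RIS invariances: lesion order, single-court limits, boundary", {
  set.seed(33)
  for (rep in 1:50) {
    rils <- rnorm(sample(2:6, 1))
    t <- rnorm(1)
    expect_equal(merge_ris(rils, t), merge_ris(rev(rils), t))
    expect_equal(merge_ris(sample(rils), t), merge_ris(rils, t))
  }
  # all on one side: plain mean
  expect_equal(merge_ris(c(1, 2, 3), 0), 2)
  expect_equal(merge_ris(c(-3, -2, -1), 0), -2)
  # a lesion exactly at T joins the positive court and enters its mean
  expect_equal(merge_ris(c(0.5, 0.9), 0.5), 0.7)
})
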