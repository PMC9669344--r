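test_that("AUC: worked examples and tie handling", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 1, 0, 1), positive = 1), 0.75)
  expect_equal(auc(c(1, 2, 10, 20), c(0, 0, 1, 1), positive = 1), 1.0)
  expect_equal(auc(rep(5, 8), rep(c(0, 1), 4), positive = 1), 0.5)
  expect_error(auc(1:4, rep(1, 4), positive = 1), "both classes")
})

test_that("AUC invariances: monotone transforms and score negation", {
  set.seed(51)
  for (rep in 1:20) {
    n <- 30
    y <- sample(0:1, n, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    s <- rnorm(n)
    a <- auc(s, y, positive = 1)
    expect_equal(auc(exp(s), y, positive = 1), a)
    expect_equal(auc(rank(s), y, positive = 1), a)
    expect_equal(auc(-s, y, positive = 1) + a, 1)
  }
})

test_that("our AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(52)
  y <- sample(0:1, 50, replace = TRUE)
  y[1:2] <- 0:1
  s <- rnorm(50) + y
  expect_equal(auc(s, y, positive = 1),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("DeLong: conventions, internal consistency, pROC agreement", {
  set.seed(53)
  y <- rep(0:1, each = 30)
  a <- rnorm(60) + y * 1.2
  b <- 0.6 * a + rnorm(60) * 0.8
  res <- delong_test(a, b, y, positive = 1)
  expect_equal(res$delta, auc(a, y, positive = 1) - auc(b, y, positive = 1))
  expect_gt(res$se, 0)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  same <- delong_test(a, a, y, positive = 1)
  expect_equal(same$p_value, 1.0)

  skip_if_not_installed("pROC")
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                       pROC::roc(y, b, quiet = TRUE, direction = "<"),
                       method = "delong", paired = TRUE)
  expect_equal(res$p_value, as.numeric(pr$p.value), tolerance = 1e-8)
})

test_that("Cohen's kappa: worked 2x2 table, perfection, and the null", {
  expect_equal(cohens_kappa(c(1, 2, 1), c(1, 2, 1)), 1.0)
  # agreement table [[20, 5], [10, 15]]: p_o 0.7, p_e 0.5, kappa 0.4
  r1 <- rep(c("a", "a", "b", "b"), c(20, 5, 10, 15))
  r2 <- rep(c("a", "b", "a", "b"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(r1, r2), 0.4)
  set.seed(54)
  x <- sample(1:2, 10000, replace = TRUE)
  z <- sample(1:2, 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(x, z)), 0.05)
  expect_equal(cohens_kappa(rep("x", 5), rep("x", 5)), 1.0)
})

test_that("Fisher's exact test: flat table, worked p, zero margin", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2)), 1.0)
  p <- fisher_exact(matrix(c(1, 11, 9, 3), 2))   # [[1, 9], [11, 3]]
  expect_equal(p, 0.002759456, tolerance = 1e-6)
  expect_equal(fisher_exact(matrix(c(0, 0, 7, 9), 2, byrow = TRUE)), 1.0)
})

test_that("the joint fit is label-antisymmetric and guards separation", {
  set.seed(55)
  d <- simulate_score_cohort(40, 1.5, 1.0, seed = 5)
  m1 <- fit_joint(d, d$class)
  m2 <- fit_joint(d, d$class, positive = "AE")   # flipped encoding
  expect_equal(unname(m1$coefficients[-1]), -unname(m2$coefficients[-1]),
               tolerance = 1e-6)
  # scores identical to the labels: complete separation, finite fallback
  sep <- tibble::tibble(ris = rep(0:1, each = 20), sdi = rep(0:1, each = 20))
  expect_warning(ms <- fit_joint(sep, rep(c("AE", "AS"), each = 20)),
                 "collinear")
  expect_true(all(is.finite(ms$coefficients)))
  expect_equal(ms$method, "ridge")
})

test_that("under null labels the joint coefficients stay small", {
  set.seed(56)
  cfs <- t(vapply(1:20, function(i) {
    d <- simulate_score_cohort(100, 0, 0, seed = 100 + i)
    fit_joint(d, d$class)$coefficients[-1]
  }, numeric(2)))
  expect_lt(max(abs(cfs)), 1)
  expect_lt(abs(mean(cfs)), 0.15)
})

test_that("evaluation reports metrics per model x split at frozen cutoffs", {
  set.seed(57)
  d <- simulate_score_cohort(30, 2.5, 2, seed = 7)
  d$split <- rep(c("train", "test"), 30)
  d$label <- d$class
  joint <- fit_joint(d[d$split == "train", ], d$label[d$split == "train"])
  d$p_joint <- predict(joint, d)
  cuts <- list(
    ris = youden_threshold(d$ris[d$split == "train"],
                           d$label[d$split == "train"]),
    sdi = youden_threshold(d$sdi[d$split == "train"],
                           d$label[d$split == "train"]),
    p_joint = joint$cutoff
  )
  rep_ <- evaluate_models(d, cuts)
  expect_s3_class(rep_, "eval_report")
  expect_equal(nrow(rep_$metrics), 6)          # 3 models x 2 splits
  expect_equal(nrow(rep_$delong), 6)           # 3 pairs x 2 splits
  expect_true(all(rep_$metrics$auc >= 0 & rep_$metrics$auc <= 1))
  wide <- report_table(rep_)
  expect_equal(nrow(wide), 4)
  p <- autoplot(rep_, scores = d)
  expect_s3_class(p, "ggplot")
})

test_that("a perfectly separating score yields training accuracy 1", {
  d <- simulate_score_cohort(25, 10, 10, seed = 8)
  d$split <- "train"
  d$label <- d$class
  joint <- fit_joint(d, d$label)
  d$p_joint <- predict(joint, d)
  cuts <- list(ris = youden_threshold(d$ris, d$label),
               sdi = youden_threshold(d$sdi, d$label),
               p_joint = joint$cutoff)
  rep_ <- evaluate_models(d, cuts)
  expect_true(all(rep_$metrics$accuracy == 1))
})
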