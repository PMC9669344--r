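# Subject-level models and evaluation statistics: the spatial-distribution
# scorer (SDI), the joint logistic model over RIS + SDI, and the ROC /
# DeLong / kappa / Fisher machinery.

#' Fit the spatial-distribution scorer (SDI)
#'
#' The same cross-validated LASSO machinery as the radiomics scorer, applied
#' to the 27-column spatial feature table; the resulting linear score is the
#' spatial distribution index (SDI).
#'
#' @inheritParams fit_lasso_cv
#' @return A `linear_scorer`.
#' @export
fit_spatial_model <- function(data, labels, k = 10, seed = 1, positive = "AS",
                              features = NULL) {
  fit_lasso_cv(data, labels, k = k, seed = seed, positive = positive,
               features = features)
}

#' Joint logistic model over RIS and SDI
#'
#' Maximum-likelihood logistic regression of the class on the two subject
#' scores. On (quasi-)separation — routine on well-separated synthetic
#' cohorts — the fit falls back to a tiny ridge penalty (1e-4) so
#' coefficients stay finite; Wald p-values are reported only for the
#' converged ML fit. Perfectly collinear scores trigger a warning and the
#' ridge fallback.
#'
#' @param data data frame with columns `ris` and `sdi`.
#' @param labels class labels (both classes present).
#' @param positive label treated as positive (default `"AS"`).
#' @return A `joint_model`: coefficients, Wald p-values (NA under the
#'   fallback), the fit method, and the training Youden cutoff on the
#'   predicted probability.
#' @export
fit_joint <- function(data, labels, positive = "AS") {
  if (!all(c("ris", "sdi") %in% names(data)))
    abort("`data` must contain columns `ris` and `sdi`")
  y <- as_binary_label(labels, positive)
  if (length(unique(y)) < 2) abort("both classes must be present")
  df <- data.frame(y = y, ris = data$ris, sdi = data$sdi)
  if (stats::sd(df$ris) > 0 && stats::sd(df$sdi) > 0 &&
      abs(cor(df$ris, df$sdi)) >= 1 - 1e-12)
    warn("RIS and SDI are perfectly collinear; fitting under the ridge fallback")
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ ris + sdi, family = binomial(), data = df),
    warning = function(w) {
      separated <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (!separated && fit$converged && all(is.finite(coef(fit))) &&
      all(abs(coef(fit)) < 1e3)) {
    cf <- coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    pv <- 2 * pnorm(-abs(cf / se))
    method <- "ml"
  } else {
    x <- as.matrix(df[, c("ris", "sdi")])
    rf <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    cc <- as.matrix(coef(rf))
    cf <- setNames(cc[, 1], c("(Intercept)", "ris", "sdi"))
    pv <- c(NA_real_, NA_real_, NA_real_)
    method <- "ridge"
  }
  prob <- 1 / (1 + exp(-(cf[1] + cf[2] * df$ris + cf[3] * df$sdi)))
  cut <- youden_threshold(prob, y, positive = 1)
  structure(
    list(coefficients = cf, p_values = setNames(pv, names(cf)),
         method = method, cutoff = cut, positive = positive),
    class = "joint_model"
  )
}

#' @export
print.joint_model <- function(x, ...) {
  cat("<joint_model> (", x$method, ") logit(p) = ",
      signif(x$coefficients[1], 4), " + ", signif(x$coefficients[2], 4),
      "*RIS + ", signif(x$coefficients[3], 4), "*SDI\n", sep = "")
  invisible(x)
}

#' @export
predict.joint_model <- function(object, newdata, ...) {
  cf <- object$coefficients
  as.vector(1 / (1 + exp(-(cf[1] + cf[2] * newdata$ris + cf[3] * newdata$sdi))))
}

#' @export
tidy.joint_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 p.value = unname(x$p_values))
}

#' @export
glance.joint_model <- function(x, ...) {
  tibble::tibble(method = x$method, cutoff = x$cutoff$threshold,
                 j_train = x$cutoff$j)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that a random positive scores above a random negative,
#' ties counting one half.
#'
#' @param scores numeric scores.
#' @param labels class labels; both classes must be present.
#' @param positive label treated as positive (default `"AS"`).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive = "AS") {
  y <- as_binary_label(labels, positive)
  if (length(unique(y)) < 2) abort("both classes must be present")
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Placement values: per-positive and per-negative components of the AUC.
delong_placements <- function(scores, y) {
  xs <- scores[y == 1]
  ys <- scores[y == 0]
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), numeric(1))
  v01 <- vapply(ys, function(x) mean((xs > x) + 0.5 * (xs == x)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors over the same subjects using the
#' placement-value covariance estimator; the difference is referred to a
#' standard normal.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels class labels shared by both.
#' @param positive label treated as positive.
#' @return A tibble: `auc_a`, `auc_b`, `delta`, `se`, `z`, `p_value`
#'   (two-sided; 1.0 by convention when both the difference and its
#'   variance are zero).
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "AS") {
  y <- as_binary_label(labels, positive)
  if (length(unique(y)) < 2) abort("both classes must be present")
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(y))
    abort("scores_a, scores_b and labels must be the same length")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- sum(y == 1)
  n <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  vd <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
        (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  if (!is.finite(vd)) vd <- 0   # a single positive or negative: no variance
  delta <- pa$auc - pb$auc
  if (vd <= 0) {
    p <- if (abs(delta) < 1e-12) 1.0 else 0.0
    z <- if (abs(delta) < 1e-12) 0.0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(vd)
    p <- 2 * pnorm(-abs(z))
  }
  tibble::tibble(auc_a = pa$auc, auc_b = pb$auc, delta = delta,
                 se = sqrt(max(vd, 0)), z = z, p_value = p)
}

#' Cohen's kappa for two raters
#'
#' `(p_o - p_e) / (1 - p_e)`; if both raters are constant and identical
#' (`p_e = 1`) the agreement is perfect by convention (kappa 1).
#'
#' @param ratings1,ratings2 equal-length categorical vectors.
#' @return Scalar kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(ratings1, ratings2) {
  if (length(ratings1) != length(ratings2)) abort("ratings differ in length")
  lev <- union(unique(ratings1), unique(ratings2))
  t1 <- factor(ratings1, levels = lev)
  t2 <- factor(ratings2, levels = lev)
  tab <- table(t1, t2)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1.0 else 0.0)
  (po - pe) / (1 - pe)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by the probability-ordering convention (sum over tables at
#' most as probable as the observed one under the hypergeometric null).
#' A zero margin gives p = 1.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    abort("`tab` must be a 2x2 matrix of non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1.0)
  fisher.test(tab)$p.value
}

metric_row <- function(scores, labels, cutoff, positive = "AS") {
  y <- as_binary_label(labels, positive)
  pred <- as.integer(scores >= cutoff)
  tibble::tibble(
    auc = auc(scores, y, positive = 1),
    accuracy = mean(pred == y),
    sensitivity = mean(pred[y == 1] == 1),
    specificity = mean(pred[y == 0] == 0)
  )
}

#' Evaluate the three models across data splits
#'
#' For each split, computes AUC, accuracy, sensitivity and specificity of
#' the radiomics (RIS), spatial (SDI) and joint (predicted probability)
#' scores at their cutoffs frozen on the training split, plus pairwise
#' DeLong comparisons within each split.
#'
#' @param scores data frame with columns `subject_id`, `split`, `label`,
#'   `ris`, `sdi`, `p_joint`.
#' @param cutoffs named list of cutoffs (numbers or [youden_threshold()]
#'   results) for `ris`, `sdi` and `p_joint`, frozen on the training split.
#' @param positive label treated as positive.
#' @return An `eval_report`: list with `metrics` (tibble model x split) and
#'   `delong` (tibble of pairwise comparisons per split).
#' @export
evaluate_models <- function(scores, cutoffs, positive = "AS") {
  need <- c("subject_id", "split", "label", "ris", "sdi", "p_joint")
  missing <- setdiff(need, names(scores))
  if (length(missing)) abort(paste0("scores table is missing: ",
                                    paste(missing, collapse = ", ")))
  cut_of <- function(nm) {
    cc <- cutoffs[[nm]]
    if (inherits(cc, "youden_cutoff")) cc$threshold else cc
  }
  models <- c(radiomics = "ris", spatial = "sdi", joint = "p_joint")
  metrics <- purrr::map_dfr(unique(scores$split), function(sp) {
    sub <- scores[scores$split == sp, ]
    if (length(unique(sub$label)) < 2) {
      warn(paste0("split '", sp, "' lacks both classes; skipped"))
      return(NULL)
    }
    purrr::map_dfr(names(models), function(mn) {
      dplyr::bind_cols(
        tibble::tibble(model = mn, split = sp),
        metric_row(sub[[models[[mn]]]], sub$label, cut_of(models[[mn]]),
                   positive)
      )
    })
  })
  delong <- purrr::map_dfr(unique(scores$split), function(sp) {
    sub <- scores[scores$split == sp, ]
    if (length(unique(sub$label)) < 2) return(NULL)
    pairs <- utils::combn(names(models), 2, simplify = FALSE)
    purrr::map_dfr(pairs, function(pr) {
      dplyr::bind_cols(
        tibble::tibble(split = sp, model_a = pr[1], model_b = pr[2]),
        delong_test(sub[[models[[pr[1]]]]], sub[[models[[pr[2]]]]],
                    sub$label, positive)
      )
    })
  })
  structure(list(metrics = metrics, delong = delong, positive = positive),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, cols = c("auc", "accuracy", "sensitivity",
                                          "specificity"),
                      names_to = "metric", values_to = "value")
}

#' @export
glance.eval_report <- function(x, ...) {
  x$metrics |>
    dplyr::filter(.data$model == "joint") |>
    tidyr::pivot_wider(names_from = "split",
                       values_from = c("auc", "accuracy", "sensitivity",
                                       "specificity"))
}

#' Wide summary table of an evaluation report
#'
#' Rows are metrics, columns model x split, the shape of a clinical
#' performance table.
#'
#' @param x an `eval_report`.
#' @return A tibble.
#' @export
report_table <- function(x) {
  stopifnot(inherits(x, "eval_report"))
  tidy(x) |>
    tidyr::pivot_wider(names_from = c("model", "split"), values_from = "value")
}

#' ROC curves for an evaluation report
#'
#' @param object an `eval_report` produced with the score table attached
#'   via [run_pipeline()] (or pass `scores`).
#' @param scores the score table used to build the report.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.eval_report <- function(object, scores, ...) {
  positive <- object$positive
  models <- c(radiomics = "ris", spatial = "sdi", joint = "p_joint")
  df <- purrr::map_dfr(unique(scores$split), function(sp) {
    sub <- scores[scores$split == sp, ]
    y <- as_binary_label(sub$label, positive)
    purrr::map_dfr(names(models), function(mn) {
      s <- sub[[models[[mn]]]]
      thr <- c(Inf, sort(unique(s), decreasing = TRUE))
      tibble::tibble(
        model = mn, split = sp,
        tpr = vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1)),
        fpr = vapply(thr, function(t) mean(s[y == 0] >= t), numeric(1))
      )
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$model)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
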