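# Feature selection and lesion-to-subject scoring: Spearman correlation
# clustering -> LASSO -> per-lesion score (RIL) -> Youden threshold T ->
# piecewise court-merged subject score (RIS).

feature_columns <- function(data) {
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          c("lesion_id", "seed"))
}

as_binary_label <- function(labels, positive) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) abort("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  as.integer(as.character(labels) == positive)
}

#' Reduce a feature table by Spearman correlation clustering
#'
#' Computes the Spearman correlation matrix of the feature columns, performs
#' average-linkage hierarchical clustering on the distance `1 - |rho|`, cuts
#' the tree so members of a cluster correlate at `|rho| >= threshold`, and
#' retains the highest-variance member of each cluster. Constant columns are
#' dropped with a warning before clustering.
#'
#' @param data data frame whose numeric columns (minus `lesion_id`) are
#'   features; identifier columns may be present and are ignored.
#' @param threshold intra-cluster absolute Spearman correlation (default 0.9).
#' @return A `correlation_reduction`: list with `retained` (feature names),
#'   `clusters` (tibble feature/cluster), `threshold`, `dropped_constant`.
#' @export
reduce_by_correlation <- function(data, threshold = 0.90) {
  feats <- feature_columns(data)
  x <- as.matrix(data[feats])
  if (nrow(x) < 2) abort("need at least 2 rows to correlate features")
  v <- apply(x, 2, var)
  constant <- feats[v == 0 | !is.finite(v)]
  if (length(constant)) {
    warn(paste0("dropping ", length(constant), " constant feature(s): ",
                paste(head(constant, 5), collapse = ", "),
                if (length(constant) > 5) ", ..." else ""))
    feats <- setdiff(feats, constant)
    x <- x[, feats, drop = FALSE]
    v <- v[feats]
  }
  if (length(feats) == 0) abort("no non-constant features left")
  if (length(feats) == 1) {
    cl <- setNames(1L, feats)
  } else {
    rho <- suppressWarnings(cor(x, method = "spearman"))
    rho[!is.finite(rho)] <- 0
    hc <- hclust(as.dist(1 - abs(rho)), method = "average")
    cl <- cutree(hc, h = 1 - threshold)
  }
  retained <- vapply(split(names(cl), cl), function(members) {
    members[which.max(v[members])]
  }, character(1))
  structure(
    list(retained = unname(retained),
         clusters = tibble::tibble(feature = names(cl), cluster = unname(cl)),
         threshold = threshold, dropped_constant = constant),
    class = "correlation_reduction"
  )
}

#' Fit an L1-penalized logistic scorer with cross-validated penalty
#'
#' Standardizes the candidate features to training mean/sd, fits the LASSO
#' logistic path, selects the penalty minimizing mean cross-validated
#' deviance over `k` seeded folds, and returns the nonzero-weight features
#' as a linear scorer. The standardization parameters are frozen in the
#' scorer so that test/validation data are scored on the training scale.
#'
#' @param data data frame of candidate features (numeric columns;
#'   `lesion_id` ignored).
#' @param labels class labels aligned to rows.
#' @param k number of cross-validation folds (>= 2; default 10).
#' @param seed seed controlling the fold assignment.
#' @param positive label treated as the positive class (default `"AS"`).
#' @param features optional explicit feature subset (e.g. the `retained`
#'   set from [reduce_by_correlation()]).
#' @return A `linear_scorer`: selected features, weights, intercept,
#'   per-feature center/scale, chosen penalty and fold seed.
#' @export
fit_lasso_cv <- function(data, labels, k = 10, seed = 1, positive = "AS",
                         features = NULL) {
  feats <- features %||% feature_columns(data)
  missing <- setdiff(feats, names(data))
  if (length(missing)) abort(paste0("features not in data: ",
                                    paste(missing, collapse = ", ")))
  x <- as.matrix(data[feats])
  y <- as_binary_label(labels, positive)
  if (length(y) != nrow(x)) abort("labels must align with rows of data")
  if (length(unique(y)) < 2) abort("labels contain a single class; cannot fit")
  if (nrow(x) < k) abort(paste0("n = ", nrow(x), " rows but k = ", k, " folds"))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  keep <- scl > 0
  if (!all(keep)) {
    warn(paste0("dropping ", sum(!keep), " zero-variance feature(s) before LASSO"))
    feats <- feats[keep]
    x <- x[, keep, drop = FALSE]
    ctr <- ctr[keep]
    scl <- scl[keep]
  }
  if (length(feats) < 2) abort("need at least 2 non-constant candidate features")
  xs <- scale(x, center = ctr, scale = scl)
  foldid <- with_seed(derive_seed(seed, "folds"),
                      sample(rep(seq_len(k), length.out = nrow(xs))))
  cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = FALSE,
                             type.measure = "deviance")
  cf <- as.matrix(coef(cvfit, s = "lambda.min"))
  nz <- which(cf[-1, 1] != 0)
  structure(
    list(features = feats[nz], weights = unname(cf[-1, 1][nz]),
         intercept = unname(cf[1, 1]),
         center = unname(ctr[nz]), scale = unname(scl[nz]),
         lambda = cvfit$lambda.min, k = k, seed = seed, positive = positive,
         n_candidates = length(feats)),
    class = "linear_scorer"
  )
}

#' @export
print.linear_scorer <- function(x, ...) {
  cat("<linear_scorer> ", length(x$features), " of ", x$n_candidates,
      " features, lambda = ", signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
tidy.linear_scorer <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$features),
    estimate = c(x$intercept, x$weights),
    center = c(NA_real_, x$center),
    scale = c(NA_real_, x$scale)
  )
}

#' @export
glance.linear_scorer <- function(x, ...) {
  tibble::tibble(n_selected = length(x$features),
                 n_candidates = x$n_candidates,
                 lambda = x$lambda, k = x$k, seed = x$seed)
}

#' Score rows with a linear scorer (RIL / SDI)
#'
#' The score is the weighted sum of the scorer's selected features after
#' standardization to the frozen training mean/sd, plus the fitted
#' intercept.
#'
#' @param data data frame containing the scorer's feature columns.
#' @param scorer a [fit_lasso_cv()] result.
#' @return Numeric vector, one score per row.
#' @export
score_ril <- function(data, scorer) {
  stopifnot(inherits(scorer, "linear_scorer"))
  missing <- setdiff(scorer$features, names(data))
  if (length(missing))
    abort(paste0("data is missing scorer feature(s): ",
                 paste(missing, collapse = ", ")))
  if (length(scorer$features) == 0) return(rep(scorer$intercept, nrow(data)))
  x <- as.matrix(data[scorer$features])
  xs <- sweep(sweep(x, 2, scorer$center), 2, scorer$scale, `/`)
  as.vector(xs %*% scorer$weights) + scorer$intercept
}

#' @export
predict.linear_scorer <- function(object, newdata, ...) {
  score_ril(newdata, object)
}

#' Youden-optimal cutoff of a score
#'
#' Scans candidate cutoffs (midpoints between adjacent sorted unique
#' scores) and returns the one maximizing the Youden index
#' J = sensitivity + specificity - 1 under the rule "positive iff
#' score >= cutoff". Ties prefer higher sensitivity, then the lower cutoff.
#'
#' @param scores numeric scores.
#' @param labels class labels; both classes must be present.
#' @param positive label treated as positive (default `"AS"`).
#' @return A `youden_cutoff`: list with `threshold`, `j`, `sensitivity`,
#'   `specificity`.
#' @export
youden_threshold <- function(scores, labels, positive = "AS") {
  y <- as_binary_label(labels, positive)
  if (length(unique(y)) < 2) abort("both classes must be present")
  u <- sort(unique(scores))
  # midpoints of adjacent unique scores, plus the two trivial cutoffs
  # (everything positive / everything negative) so J is never below 0
  gap <- if (length(u) >= 2) min(diff(u)) / 2 else 1
  cand <- unique(c(u[1],
                   if (length(u) >= 2) (head(u, -1) + tail(u, -1)) / 2,
                   u[length(u)] + gap))
  sens <- vapply(cand, function(t) mean(scores[y == 1] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(scores[y == 0] < t), numeric(1))
  j <- sens + spec - 1
  best <- order(-j, -sens, cand)[1]
  structure(list(threshold = cand[best], j = j[best],
                 sensitivity = sens[best], specificity = spec[best]),
            class = "youden_cutoff")
}

#' @export
print.youden_cutoff <- function(x, ...) {
  cat("<youden_cutoff> T = ", signif(x$threshold, 5), " (J = ",
      signif(x$j, 4), ")\n", sep = "")
  invisible(x)
}

#' Merge per-lesion scores into one subject score (RIS)
#'
#' Lesions are split into a positive court (RIL >= T) and a negative court
#' (RIL < T). The court whose summed absolute distance to T is larger wins
#' (ties, including the single-court limits, go to the positive court), and
#' the subject score is the mean RIL of the winning court. A single lesion
#' therefore yields its own RIL.
#'
#' @param rils numeric per-lesion scores of one scan (length >= 1).
#' @param threshold the cutoff T, or a [youden_threshold()] result.
#' @return The scalar subject score.
#' @examples
#' merge_ris(c(0.2, 0.8, 0.9), 0.5)  # 0.85
#' merge_ris(c(0.4, 0.6), 0.5)       # tie -> positive court -> 0.6
#' @export
merge_ris <- function(rils, threshold) {
  if (inherits(threshold, "youden_cutoff")) threshold <- threshold$threshold
  if (length(rils) < 1) abort("at least one lesion score is required")
  if (any(!is.finite(rils))) abort("non-finite lesion scores")
  pos <- rils >= threshold
  d_pos <- sum(abs(rils[pos] - threshold))
  d_neg <- sum(abs(rils[!pos] - threshold))
  court <- if (d_pos >= d_neg) rils[pos] else rils[!pos]
  if (length(court) == 0) abort("internal error: winning court is empty")
  mean(court)
}

#' Per-subject RIS table from a scored lesion table
#'
#' @param lesion_scores data frame with `subject_id` and a `ril` column.
#' @param threshold the cutoff T (or [youden_threshold()] result).
#' @return Tibble: `subject_id`, `ris`.
#' @export
merge_ris_by_subject <- function(lesion_scores, threshold) {
  lesion_scores |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ris = merge_ris(.data$ril, threshold), .groups = "drop")
}

#' Serialize a fitted scorer (plus optional cutoff) to JSON
#'
#' @param scorer a `linear_scorer`.
#' @param path file to write.
#' @param cutoff optional [youden_threshold()] result stored alongside.
#' @return `path`, invisibly.
#' @export
write_scorer_json <- function(scorer, path, cutoff = NULL) {
  obj <- unclass(scorer)
  if (!is.null(cutoff)) obj$cutoff <- unclass(cutoff)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
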