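# End-to-end orchestration: simulate -> extract -> select/fit -> merge ->
# joint -> evaluate, with the scanner-stratified 3:1 split and one master
# seed funnelled through every stochastic stage.

#' Pipeline run configuration
#'
#' Every analysis choice the pipeline makes in one serializable object:
#' phantom settings, cohort sizes, the split ratio, LASSO settings,
#' discretization, the component-size floor, and the positive-class
#' convention.
#'
#' @param phantom a [phantom_config()].
#' @param n_dev_AE,n_dev_AS development-era subjects per class (split 3:1
#'   into train/test).
#' @param n_val_AE,n_val_AS independent-validation subjects per class
#'   (never entering training).
#' @param scanner_mix named scanner probabilities.
#' @param test_fraction fraction of each cohort x scanner stratum assigned
#'   to the test split (default 1/4, i.e. a 3:1 train:test ratio).
#' @param corr_threshold correlation-reduction threshold.
#' @param lasso_k cross-validation folds.
#' @param discretize a [discretize_config()].
#' @param min_volume lesion component floor, mm^3.
#' @param families radiomics families to extract.
#' @param positive positive class (default `"AS"`).
#' @param seed master seed; all per-stage seeds derive from it.
#' @param input_dir optional directory of a previously written cohort to
#'   load instead of simulating (see [write_phantom_cohort()]).
#' @param out_dir optional directory for artifacts (tables, models, report).
#' @return A `run_config` object.
#' @export
run_config <- function(phantom = phantom_config(),
                       n_dev_AE = 40, n_dev_AS = 40,
                       n_val_AE = 0, n_val_AS = 0,
                       scanner_mix = c(A = 0.4, B = 0.4, C = 0.2),
                       test_fraction = 0.25,
                       corr_threshold = 0.90,
                       lasso_k = 10,
                       discretize = discretize_config(),
                       min_volume = 8,
                       families = c("morphology", "statistics", "histogram",
                                    "texture"),
                       positive = "AS",
                       seed = 1L,
                       input_dir = NULL,
                       out_dir = NULL) {
  structure(
    list(phantom = phantom, n_dev_AE = n_dev_AE, n_dev_AS = n_dev_AS,
         n_val_AE = n_val_AE, n_val_AS = n_val_AS, scanner_mix = scanner_mix,
         test_fraction = test_fraction, corr_threshold = corr_threshold,
         lasso_k = lasso_k, discretize = discretize, min_volume = min_volume,
         families = families, positive = positive, seed = as.integer(seed),
         input_dir = input_dir, out_dir = out_dir),
    class = "run_config"
  )
}

#' Scanner-stratified train/test split
#'
#' Within each cohort x scanner stratum, `round(n / 4)` subjects (for the
#' default 3:1 ratio) are drawn into the test split; strata smaller than 4
#' go entirely to training with a warning; per-cohort totals are then
#' balanced to `round(cohort_n / 4)` by adjusting the largest strata. The
#' draw is seeded and reproducible.
#'
#' @param roster data frame with `subject_id`, `class`, `scanner_id`.
#' @param test_fraction test share (default 0.25).
#' @param seed integer seed.
#' @return The roster with an added `split` column (`"train"`/`"test"`).
#' @export
stratified_split <- function(roster, test_fraction = 0.25, seed = 1L) {
  if (nrow(roster) == 0) {
    return(dplyr::mutate(roster, split = character(0)))
  }
  roster$split <- "train"
  for (cl in unique(roster$class)) {
    rows_c <- which(roster$class == cl)
    target <- round(length(rows_c) * test_fraction)
    strata <- split(rows_c, roster$scanner_id[rows_c])
    n_test <- vapply(strata, function(ix) {
      if (length(ix) < 4) 0L else as.integer(round(length(ix) * test_fraction))
    }, integer(1))
    small <- names(strata)[vapply(strata, length, integer(1)) < 4]
    if (length(small))
      warn(paste0("cohort ", cl, ": stratum(s) ",
                  paste(small, collapse = ", "),
                  " smaller than 4; assigned wholly to training"))
    # residual balancing toward the cohort-level target
    ord <- order(-vapply(strata, length, integer(1)))
    excess <- sum(n_test) - target
    i <- 1L
    while (excess != 0 && length(strata) > 0) {
      s <- ord[(i - 1L) %% length(ord) + 1L]
      if (excess > 0 && n_test[s] > 0) {
        n_test[s] <- n_test[s] - 1L
        excess <- excess - 1L
      } else if (excess < 0 && n_test[s] < length(strata[[s]]) &&
                 length(strata[[s]]) >= 4) {
        n_test[s] <- n_test[s] + 1L
        excess <- excess + 1L
      }
      i <- i + 1L
      if (i > 1000L) break
    }
    for (s in seq_along(strata)) {
      if (n_test[s] > 0) {
        pick <- with_seed(derive_seed(seed, "split", cl, names(strata)[s]),
                          sample(strata[[s]], n_test[s]))
        roster$split[pick] <- "test"
      }
    }
  }
  roster
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage ", name, ": ", conditionMessage(e)))
  })
}

#' Fit all models on extracted feature tables
#'
#' The training half of the pipeline, separated so it can run on any
#' feature tables (simulated or loaded): correlation reduction and LASSO on
#' training lesions, the lesion-level Youden threshold T, court-merged RIS,
#' the spatial LASSO (SDI), subject-level cutoffs, and the joint logistic
#' model. Only training-split rows influence standardization, selection,
#' thresholds and fits.
#'
#' @param radiomics per-lesion feature table (from [extract_radiomics()]).
#' @param spatial per-scan spatial table (from [extract_spatial()]).
#' @param roster subject table with `subject_id`, `class`, `split`
#'   (`"train"`, `"test"`, and optionally `"validation"`).
#' @param corr_threshold,lasso_k,positive,seed as in [run_config()].
#' @return List: `ril_scorer`, `t_lesion` (Youden T on lesion scores),
#'   `sdi_scorer`, cutoffs, `joint`, and the per-subject `scores` table.
#' @export
pipeline_train <- function(radiomics, spatial, roster,
                           corr_threshold = 0.90, lasso_k = 10,
                           positive = "AS", seed = 1L) {
  roster <- dplyr::as_tibble(roster)
  radiomics <- dplyr::select(radiomics, -dplyr::any_of(c("class", "split")))
  spatial <- dplyr::select(spatial, -dplyr::any_of(c("class", "split")))
  rad <- dplyr::inner_join(radiomics,
                           roster[c("subject_id", "class", "split")],
                           by = "subject_id")
  train_lesions <- rad[rad$split == "train", ]
  red <- stage("reduce", reduce_by_correlation(
    dplyr::select(train_lesions, -dplyr::any_of(c("class", "split"))),
    threshold = corr_threshold))
  ril_scorer <- stage("lasso-radiomics", fit_lasso_cv(
    train_lesions, train_lesions$class, k = lasso_k,
    seed = derive_seed(seed, "lasso", "ril"), positive = positive,
    features = red$retained))
  rad$ril <- score_ril(rad, ril_scorer)
  t_lesion <- stage("youden-lesion", youden_threshold(
    rad$ril[rad$split == "train"], rad$class[rad$split == "train"],
    positive = positive))
  ris_tbl <- merge_ris_by_subject(rad, t_lesion)
  spa <- dplyr::inner_join(spatial, roster[c("subject_id", "class", "split")],
                           by = "subject_id")
  spa_train <- spa[spa$split == "train", ]
  sdi_scorer <- stage("lasso-spatial", fit_spatial_model(
    dplyr::select(spa_train, -dplyr::any_of(c("class", "split"))),
    spa_train$class, k = lasso_k,
    seed = derive_seed(seed, "lasso", "sdi"), positive = positive))
  spa$sdi <- score_ril(spa, sdi_scorer)
  scores <- roster |>
    dplyr::left_join(ris_tbl, by = "subject_id") |>
    dplyr::left_join(spa[c("subject_id", "sdi")], by = "subject_id") |>
    dplyr::rename(label = "class")
  if (any(is.na(scores$ris) | is.na(scores$sdi)))
    abort("some subjects have no lesion above the size floor; cannot score")
  train <- scores[scores$split == "train", ]
  ris_cut <- youden_threshold(train$ris, train$label, positive = positive)
  sdi_cut <- youden_threshold(train$sdi, train$label, positive = positive)
  joint <- stage("joint", fit_joint(train, train$label, positive = positive))
  scores$p_joint <- predict(joint, scores)
  list(reduction = red, ril_scorer = ril_scorer, t_lesion = t_lesion,
       sdi_scorer = sdi_scorer, ris_cutoff = ris_cut, sdi_cutoff = sdi_cut,
       joint = joint, scores = scores)
}

#' Run the whole pipeline on a synthetic (or loaded) cohort
#'
#' Simulates (or loads) the development and independent-validation
#' cohorts, splits the development era 3:1 by scanner within each class,
#' extracts radiomics and spatial features, fits every model on the
#' training split only, and evaluates all three models on every split.
#' Rerunning with the same configuration reproduces every table bit for
#' bit.
#'
#' @param config a [run_config()].
#' @return A `radspat_run`: the config, roster, feature tables, fitted
#'   models, per-subject score table, and the [evaluate_models()] report.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (!is.null(config$input_dir)) {
    if (!dir.exists(config$input_dir) ||
        !file.exists(file.path(config$input_dir, "truth.csv")))
      abort(paste0("stage load: cohort directory or truth.csv missing at ",
                   config$input_dir))
    cohort <- stage("load", read_phantom_cohort(config$input_dir))
    dev <- cohort
    val <- list(subjects = list(),
                truth = cohort$truth[0, ])
  } else {
    dev <- stage("simulate", simulate_cohort(
      config$phantom, config$n_dev_AE, config$n_dev_AS,
      scanner_mix = config$scanner_mix, seed = derive_seed(seed, "dev")))
    val <- stage("simulate", simulate_cohort(
      config$phantom, config$n_val_AE, config$n_val_AS,
      scanner_mix = config$scanner_mix, seed = derive_seed(seed, "val"),
      id_prefix = "V"))
  }
  roster <- stratified_split(dev$truth, test_fraction = config$test_fraction,
                             seed = derive_seed(seed, "split"))
  if (nrow(val$truth)) {
    roster <- dplyr::bind_rows(roster,
                               dplyr::mutate(val$truth, split = "validation"))
  }
  subjects <- c(dev$subjects, val$subjects)
  radiomics <- stage("extract-radiomics", extract_radiomics(
    subjects, cfg = config$discretize, families = config$families,
    min_volume = config$min_volume))
  spatial <- stage("extract-spatial", extract_spatial(
    subjects, min_volume = config$min_volume))
  fit <- pipeline_train(radiomics, spatial, roster,
                        corr_threshold = config$corr_threshold,
                        lasso_k = config$lasso_k,
                        positive = config$positive, seed = seed)
  report <- stage("evaluate", evaluate_models(
    fit$scores,
    cutoffs = list(ris = fit$ris_cutoff, sdi = fit$sdi_cutoff,
                   p_joint = fit$joint$cutoff),
    positive = config$positive))
  run <- structure(
    c(list(config = config, roster = roster, radiomics = radiomics,
           spatial = spatial, report = report), fit),
    class = "radspat_run"
  )
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

#' @export
print.radspat_run <- function(x, ...) {
  cat("<radspat_run> ", nrow(x$roster), " subjects (",
      sum(x$roster$split == "train"), " train / ",
      sum(x$roster$split == "test"), " test / ",
      sum(x$roster$split == "validation"), " validation), ",
      nrow(x$radiomics), " lesions\n", sep = "")
  cat("RIL: ", length(x$ril_scorer$features), " features; T = ",
      signif(x$t_lesion$threshold, 4), ". SDI: ",
      length(x$sdi_scorer$features), " features.\n", sep = "")
  print(x$report)
  invisible(x)
}

#' @export
glance.radspat_run <- function(x, ...) {
  glance(x$report)
}

#' Write all artifacts of a pipeline run
#'
#' Feature tables and scores as CSV, models and the report as JSON, plus
#' the configuration; everything needed to audit the run.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$radiomics, file.path(dir, "radiomics_features.csv"))
  readr::write_csv(run$spatial, file.path(dir, "spatial_features.csv"))
  readr::write_csv(run$scores, file.path(dir, "subject_scores.csv"))
  readr::write_csv(run$report$metrics, file.path(dir, "metrics.csv"))
  readr::write_csv(run$report$delong, file.path(dir, "delong.csv"))
  readr::write_csv(report_table(run$report), file.path(dir, "report_table.csv"))
  write_scorer_json(run$ril_scorer, file.path(dir, "model_ril.json"),
                    cutoff = run$t_lesion)
  write_scorer_json(run$sdi_scorer, file.path(dir, "model_sdi.json"),
                    cutoff = run$sdi_cutoff)
  jsonlite::write_json(
    list(coefficients = as.list(run$joint$coefficients),
         p_values = as.list(run$joint$p_values),
         method = run$joint$method,
         cutoff = unclass(run$joint$cutoff)),
    file.path(dir, "model_joint.json"), auto_unbox = TRUE, digits = NA)
  cfg <- rapply(unclass(run$config), unclass, how = "replace")
  jsonlite::write_json(cfg, file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(dir)
}
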