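# Table-level cohort simulators: feature matrices and subject scores with
# known planted structure. These exercise the selection / merging / joint
# machinery directly, at a fraction of the cost of image-level phantoms, and
# are what the parameter-recovery and model-ordering checks run on.

#' Simulate a feature table with planted informative columns
#'
#' Balanced two-class cohort; `n_informative` features carry a mean shift of
#' `effect` (in within-class SD units) for the positive class, the rest are
#' standard-normal noise.
#'
#' @param n_per_class subjects per class.
#' @param n_features total feature columns.
#' @param n_informative number of planted informative features (first
#'   columns).
#' @param effect standardized mean shift of the informative features.
#' @param seed integer seed.
#' @param classes the two class labels (negative, positive).
#' @return Tibble: `subject_id`, `class`, `feat_001` ...
#' @export
simulate_feature_cohort <- function(n_per_class, n_features,
                                    n_informative = 0, effect = 0,
                                    seed = 1, classes = c("AE", "AS")) {
  stopifnot(n_informative <= n_features)
  with_seed(seed, {
    n <- 2 * n_per_class
    cls <- rep(classes, each = n_per_class)
    x <- matrix(rnorm(n * n_features), n, n_features)
    if (n_informative > 0) {
      shift <- matrix(0, n, n_informative)
      shift[cls == classes[2], ] <- effect
      x[, seq_len(n_informative)] <- x[, seq_len(n_informative)] + shift
    }
    colnames(x) <- sprintf("feat_%03d", seq_len(n_features))
    dplyr::bind_cols(
      tibble::tibble(subject_id = sprintf("T%04d", seq_len(n)), class = cls),
      tibble::as_tibble(x)
    )
  })
}

#' Simulate subject scores for two channels with known signal
#'
#' Generates per-subject `ris` and `sdi` scores as independent Gaussian
#' channels with class separations `effect_ris` and `effect_sdi` (in SD
#' units). With both effects 0 the scores carry no class information.
#'
#' @param n_per_class subjects per class.
#' @param effect_ris,effect_sdi standardized separations of the channels.
#' @param seed integer seed.
#' @param classes the two class labels (negative, positive).
#' @return Tibble: `subject_id`, `class`, `ris`, `sdi`.
#' @export
simulate_score_cohort <- function(n_per_class, effect_ris, effect_sdi,
                                  seed = 1, classes = c("AE", "AS")) {
  with_seed(seed, {
    n <- 2 * n_per_class
    y <- rep(c(0, 1), each = n_per_class)
    tibble::tibble(
      subject_id = sprintf("T%04d", seq_len(n)),
      class = rep(classes, each = n_per_class),
      ris = rnorm(n) + effect_ris * y,
      sdi = rnorm(n) + effect_sdi * y
    )
  })
}
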