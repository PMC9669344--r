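#' Extract the full radiomics vector for one lesion
#'
#' Runs the four feature families on one lesion and returns the 351 values in
#' [feature_catalog()] order. All values are finite: degenerate inputs
#' (constant intensity, single-voxel masks, directions without pairs) resolve
#' to the documented fallback conventions rather than `NaN`, so downstream
#' design matrices are always usable.
#'
#' @param lesion a [lesion_image()].
#' @param cfg a [discretize_config()] shared by histogram and texture families.
#' @param families which families to compute (default all four); the returned
#'   vector is restricted accordingly.
#' @param slice_axis array axis treated as the slice axis for 2D texture
#'   aggregations.
#' @return Named numeric vector (length 351 for the full catalog).
#' @examples
#' les <- lesion_image(array(rnorm(5^3), c(5, 5, 5)),
#'                     array(TRUE, c(5, 5, 5)))
#' length(extract_features(les))  # 351
#' @export
extract_features <- function(lesion, cfg = discretize_config(),
                             families = c("morphology", "statistics",
                                          "histogram", "texture"),
                             slice_axis = 3L) {
  stopifnot(inherits(lesion, "lesion_image"))
  families <- match.arg(families, several.ok = TRUE)
  out <- c(
    if ("morphology" %in% families) morphology_features(lesion),
    if ("statistics" %in% families) intensity_statistics(lesion),
    if ("histogram" %in% families) histogram_features(lesion, cfg),
    if ("texture" %in% families) texture_features(lesion, cfg, slice_axis)
  )
  bad <- !is.finite(out)
  if (any(bad)) {
    abort(paste0("non-finite feature value(s) for lesion ",
                 lesion$subject_id, "/", lesion$lesion_id, ": ",
                 paste(names(out)[bad], collapse = ", ")))
  }
  out
}

#' Radiomics feature table for a cohort
#'
#' Splits every subject's mask into lesions, extracts features per lesion,
#' and stacks the results into one tidy table (one row per lesion).
#'
#' @param subjects a list of phantom subjects (see [simulate_subject()]) or of
#'   lists with elements `image`, `mask`, `spacing`, `subject_id`.
#' @param cfg a [discretize_config()].
#' @param families passed to [extract_features()].
#' @param min_volume smallest lesion component retained, mm^3.
#' @return A tibble: `subject_id`, `lesion_id`, then one column per feature.
#' @export
extract_radiomics <- function(subjects, cfg = discretize_config(),
                              families = c("morphology", "statistics",
                                           "histogram", "texture"),
                              min_volume = 8) {
  rows <- purrr::map_dfr(subjects, function(s) {
    lesions <- split_lesions(s$image, s$mask, s$spacing,
                             subject_id = s$subject_id, min_volume = min_volume)
    purrr::map_dfr(lesions, function(l) {
      fv <- extract_features(l, cfg, families = families)
      dplyr::bind_cols(
        tibble::tibble(subject_id = l$subject_id, lesion_id = l$lesion_id),
        tibble::as_tibble_row(as.list(fv))
      )
    })
  })
  rows
}
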