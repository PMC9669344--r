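#' The 351-feature radiomics catalog
#'
#' Enumerates every feature the extractor emits, in extraction order, with
#' its family (29 morphology, 20 statistics, 30 histogram, 272 texture),
#' subfamily and aggregation. Family counts and the 351 total are asserted
#' at construction.
#'
#' @return A tibble with columns `feature`, `family`, `subfamily`,
#'   `aggregation`.
#' @examples
#' dplyr::count(feature_catalog(), family)
#' @export
feature_catalog <- function() {
  tex <- list(
    c("glcm", "2d_avg"), c("glcm", "2d_mrg"), c("glcm", "3d_avg"), c("glcm", "3d_mrg"),
    c("glrlm", "2d_avg"), c("glrlm", "2d_mrg"), c("glrlm", "3d_avg"), c("glrlm", "3d_mrg"),
    c("glszm", "2d"), c("glszm", "3d"),
    c("gldzm", "2d"), c("gldzm", "3d"),
    c("ngtdm", "2d"), c("ngtdm", "3d"),
    c("ngldm", "2d"), c("ngldm", "3d")
  )
  base_of <- list(
    glcm = glcm_base_names, glrlm = glrlm_base_names, glszm = glszm_base_names,
    gldzm = gldzm_base_names, ngtdm = ngtdm_base_names, ngldm = ngldm_base_names
  )
  tex_rows <- purrr::map_dfr(tex, function(ta) {
    tibble::tibble(
      feature = paste0(ta[1], "_", base_of[[ta[1]]], "_", ta[2]),
      family = "texture", subfamily = ta[1], aggregation = ta[2]
    )
  })
  cat <- dplyr::bind_rows(
    tibble::tibble(feature = morphology_feature_names, family = "morphology",
                   subfamily = "morph", aggregation = "none"),
    tibble::tibble(feature = intensity_feature_names, family = "statistics",
                   subfamily = "stat", aggregation = "none"),
    tibble::tibble(feature = histogram_feature_names, family = "histogram",
                   subfamily = ifelse(startsWith(histogram_feature_names, "ivh"),
                                      "ivh", "ih"),
                   aggregation = "none"),
    tex_rows
  )
  counts <- table(cat$family)
  stopifnot(
    counts[["morphology"]] == 29, counts[["statistics"]] == 20,
    counts[["histogram"]] == 30, counts[["texture"]] == 272,
    nrow(cat) == 351, !anyDuplicated(cat$feature)
  )
  cat
}

#' Write the catalog as a machine-readable JSON manifest
#'
#' The catalog is this package's interpretation of a 29/20/30/272 family
#' split under IBSI-style definitions; the manifest records it explicitly
#' (feature ids, families, aggregations, and the discretization defaults).
#'
#' @param path file to write.
#' @param cfg the [discretize_config()] recorded alongside the catalog.
#' @return `path`, invisibly.
#' @export
write_catalog_manifest <- function(path, cfg = discretize_config()) {
  cat <- feature_catalog()
  jsonlite::write_json(
    list(
      n_features = nrow(cat),
      family_counts = as.list(table(cat$family)),
      discretization = list(method = cfg$method, value = cfg$value),
      note = paste("Feature ids and definitions are this package's IBSI-style",
                   "interpretation of the four-family catalog."),
      features = cat
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
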