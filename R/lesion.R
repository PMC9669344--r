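#' Bundle one lesion's intensities, mask and voxel spacing
#'
#' The unit object radiomics feature extraction operates on: an intensity
#' grid, a congruent binary mask marking the lesion, and the physical voxel
#' spacing in millimetres.
#'
#' @param image 3D numeric array of intensities (arbitrary units).
#' @param mask 3D logical (or 0/1) array, same dimensions as `image`.
#' @param spacing numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param subject_id,lesion_id optional identifiers carried into feature rows.
#' @return An object of class `lesion_image`.
#' @examples
#' img <- array(rnorm(27), c(3, 3, 3))
#' msk <- array(TRUE, c(3, 3, 3))
#' les <- lesion_image(img, msk, spacing = c(1, 1, 1))
#' @export
lesion_image <- function(image, mask, spacing = c(1, 1, 1),
                         subject_id = NA_character_, lesion_id = NA_integer_) {
  if (length(dim(image)) != 3L) abort("`image` must be a 3D array")
  mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(image), dim(mask))) abort("`image` and `mask` grids are not congruent")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    abort("`spacing` must be 3 positive numbers (mm)")
  if (!any(mask)) abort("`mask` is empty: a lesion must contain at least one voxel")
  if (any(!is.finite(image[mask]))) abort("non-finite intensities inside the mask")
  structure(
    list(image = image, mask = mask, spacing = spacing,
         subject_id = subject_id, lesion_id = as.integer(lesion_id)),
    class = "lesion_image"
  )
}

#' @export
print.lesion_image <- function(x, ...) {
  cat("<lesion_image> ", sum(x$mask), " voxels, grid ",
      paste(dim(x$image), collapse = "x"),
      ", spacing ", paste(signif(x$spacing, 3), collapse = "x"), " mm\n", sep = "")
  invisible(x)
}

#' Split a scan mask into per-lesion objects
#'
#' Labels 26-connected components of the lesion mask, discards components
#' smaller than `min_volume` mm^3, and crops each remaining component (with a
#' margin for neighbourhood-based features) into its own [lesion_image()].
#'
#' @param image,mask,spacing as in [lesion_image()].
#' @param subject_id identifier stamped on each lesion.
#' @param min_volume smallest component retained, mm^3 (default 8).
#' @param margin crop margin in voxels around each component's bounding box.
#' @return A list of `lesion_image` objects (possibly empty).
#' @export
split_lesions <- function(image, mask, spacing = c(1, 1, 1),
                          subject_id = NA_character_, min_volume = 8,
                          margin = 4L) {
  mask <- array(as.logical(mask), dim(mask))
  lab <- label_components_array(mask, connectivity = 26L)
  k <- max(lab)
  if (k == 0L) return(list())
  vv <- prod(spacing)
  out <- list()
  for (i in seq_len(k)) {
    comp <- lab == i
    if (sum(comp) * vv < min_volume) next
    ix <- bbox_index(comp, margin = margin)
    out[[length(out) + 1L]] <- lesion_image(
      image[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
      comp[ix[[1]], ix[[2]], ix[[3]], drop = FALSE],
      spacing = spacing, subject_id = subject_id,
      lesion_id = length(out) + 1L
    )
  }
  out
}
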