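# The 27 per-scan spatial-distribution features: lesion voxel counts in the
# 16 atlas regions, lesion count, mean/max/summed lesion sizes, and counts
# of lesions in seven size bins.

spatial_feature_names <- c(
  sprintf("spat_region_%02d", 1:16),
  "spat_n_lesions", "spat_size_mean", "spat_size_max", "spat_size_sum",
  "spat_bin_8_80", "spat_bin_80_160", "spat_bin_160_320", "spat_bin_320_640",
  "spat_bin_640_1280", "spat_bin_1280_2560", "spat_bin_ge_2560"
)

size_bin_breaks <- c(8, 80, 160, 320, 640, 1280, 2560, Inf)

#' Binarize a probabilistic lesion mask
#'
#' Spatially normalized lesion masks are fractional; thresholding at 0.5
#' (a voxel is lesion iff its value is >= 0.5) avoids the apparent lesion
#' expansion that interpolation causes.
#'
#' @param mask 3D numeric array with values in `[0, 1]`.
#' @param threshold inclusion threshold (default 0.5; boundary included).
#' @return Logical array.
#' @export
binarize_mask <- function(mask, threshold = 0.5) {
  if (any(mask < 0 | mask > 1, na.rm = TRUE))
    abort("probabilistic mask values must lie in [0, 1]")
  array(mask >= threshold, dim(mask))
}

#' Label lesion instances and their physical sizes
#'
#' 26-connected components of the binary mask; component size is voxel
#' count times voxel volume. Components below `min_volume` mm^3 are
#' discarded (and reported via a message), mirroring the segmentation rule
#' that ignores tiny lesions.
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing, mm.
#' @param min_volume exclusion floor, mm^3 (default 8).
#' @param connectivity 26 (default) or 6.
#' @return A list: `labels` (integer array; retained components relabelled
#'   `1..k`) and `sizes` (tibble: `lesion`, `n_voxels`, `volume`).
#' @export
label_components <- function(mask, spacing = c(1, 1, 1), min_volume = 8,
                             connectivity = 26L) {
  mask <- array(as.logical(mask), dim(mask))
  lab <- label_components_array(mask, connectivity = connectivity)
  vv <- prod(spacing)
  k <- max(lab)
  if (k == 0L) {
    return(list(labels = lab,
                sizes = tibble::tibble(lesion = integer(), n_voxels = integer(),
                                       volume = numeric())))
  }
  nvox <- tabulate(lab[lab > 0L], nbins = k)
  vol <- nvox * vv
  keep <- which(vol >= min_volume)
  if (length(keep) < k) {
    rlang::inform(paste0("discarding ", k - length(keep),
                         " component(s) below ", min_volume, " mm^3"))
  }
  out <- array(0L, dim(mask))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  list(labels = out,
       sizes = tibble::tibble(lesion = seq_along(keep),
                              n_voxels = nvox[keep], volume = vol[keep]))
}

#' The 27 spatial-distribution features for one scan
#'
#' Counts lesion voxels per atlas region (16 values), then lesion-instance
#' statistics after the `< 8` mm^3 exclusion: lesion count, mean/max/summed
#' sizes (mm^3), and lesion counts in the seven half-open size bins
#' `[8,80), [80,160), [160,320), [320,640), [640,1280), [1280,2560),
#' [2560, Inf)`. An empty mask yields all zeros. Lesion voxels lying on
#' atlas background (label 0) enter the totals but not the region counts,
#' with a warning.
#'
#' @param mask binary (or probabilistic, see [binarize_mask()]) lesion mask.
#' @param atlas integer array of region labels 0..16, congruent with `mask`.
#' @param spacing voxel spacing, mm.
#' @param min_volume component exclusion floor, mm^3.
#' @return Named numeric vector of length 27.
#' @export
spatial_vector <- function(mask, atlas, spacing = c(1, 1, 1), min_volume = 8) {
  if (!identical(dim(mask), dim(atlas))) abort("mask and atlas grids differ")
  if (is.double(mask) && any(mask > 0 & mask < 1))
    mask <- binarize_mask(mask)
  mask <- array(as.logical(mask), dim(mask))
  lc <- label_components(mask, spacing, min_volume = min_volume)
  kept <- lc$labels > 0L
  region <- atlas[kept]
  if (any(region == 0L))
    warn(paste0(sum(region == 0L),
                " lesion voxel(s) on atlas background; excluded from region counts"))
  reg_counts <- tabulate(region[region > 0L], nbins = 16L)
  sizes <- lc$sizes$volume
  n <- length(sizes)
  bins <- if (n) tabulate(findInterval(sizes, size_bin_breaks), nbins = 7L)
          else rep(0L, 7L)
  setNames(c(
    reg_counts,
    n,
    if (n) mean(sizes) else 0,
    if (n) max(sizes) else 0,
    sum(sizes),
    bins
  ), spatial_feature_names)
}

#' Spatial feature table for a cohort
#'
#' @param subjects list of phantom subjects (or lists with `mask`, `atlas`,
#'   `spacing`, `subject_id`).
#' @param min_volume component exclusion floor, mm^3.
#' @return Tibble: `subject_id` plus the 27 spatial feature columns.
#' @export
extract_spatial <- function(subjects, min_volume = 8) {
  purrr::map_dfr(subjects, function(s) {
    sv <- spatial_vector(s$mask, s$atlas, s$spacing, min_volume = min_volume)
    dplyr::bind_cols(tibble::tibble(subject_id = s$subject_id),
                     tibble::as_tibble_row(as.list(sv)))
  })
}
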