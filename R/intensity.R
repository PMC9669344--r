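# Intensity-based statistical features (18) plus the local/global intensity
# peak pair (means over a 1 cm^3 spherical neighbourhood).

intensity_feature_names <- c(
  "stat_mean", "stat_var", "stat_skew", "stat_kurt", "stat_median",
  "stat_min", "stat_p10", "stat_p90", "stat_max", "stat_iqr", "stat_range",
  "stat_mad", "stat_rmad", "stat_medad", "stat_cov", "stat_qcod",
  "stat_energy", "stat_rms", "stat_peak_local", "stat_peak_global"
)

# Offsets (in voxels) of voxel centres within a sphere of radius r_mm.
sphere_offsets <- function(spacing, r_mm = (3 / (4 * pi))^(1 / 3) * 10) {
  r <- floor(r_mm / spacing)
  g <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d <- sqrt((g$dx * spacing[1])^2 + (g$dy * spacing[2])^2 + (g$dz * spacing[3])^2)
  as.matrix(g[d <= r_mm, , drop = FALSE])
}

# Mean image intensity over the spherical neighbourhood of every voxel
# (neighbourhood truncated at the grid edge).
sphere_means <- function(img, spacing) {
  offs <- sphere_offsets(spacing)
  acc <- array(0, dim(img))
  cnt <- array(0, dim(img))
  for (r in seq_len(nrow(offs))) {
    s <- shift3(img, offs[r, ], fill = NA)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  acc / cnt
}

#' Intensity-based statistical features for one lesion
#'
#' The 20 first-order features: mean, variance, skewness, excess kurtosis,
#' median, minimum, 10th/90th percentile, maximum, interquartile range,
#' range, mean and robust mean absolute deviation, median absolute
#' deviation, coefficient of variation, quartile coefficient of dispersion,
#' energy, root mean square, and the local/global intensity peaks (mean over
#' a 1 cm^3 sphere centred at the hottest voxel / maximised over all masked
#' voxels). Moment ratios of a constant region are 0 by policy.
#'
#' @param lesion a [lesion_image()].
#' @return Named numeric vector of length 20.
#' @export
intensity_statistics <- function(lesion) {
  x <- lesion$image[lesion$mask]
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n                       # population variance
  s <- sqrt(v)
  skew <- if (s > 0) sum((x - mu)^3) / n / s^3 else 0
  kurt <- if (s > 0) sum((x - mu)^4) / n / s^4 - 3 else 0
  q <- quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  iqr <- q[4] - q[2]
  rmad_set <- x[x >= q[1] & x <= q[5]]
  rmad <- mean(abs(rmad_set - mean(rmad_set)))
  cov_ <- if (mu != 0 && s > 0) s / mu else 0
  qcod <- if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0
  sm <- sphere_means(lesion$image, lesion$spacing)
  masked_sm <- sm[lesion$mask]
  hot <- which(x == max(x))
  peak_local <- max(masked_sm[hot])
  peak_global <- max(masked_sm)
  setNames(c(
    mu, v, skew, kurt, q[3], min(x), q[1], q[5], max(x), iqr,
    max(x) - min(x), mean(abs(x - mu)), rmad, mean(abs(x - q[3])),
    cov_, qcod, sum(x^2), sqrt(mean(x^2)), peak_local, peak_global
  ), intensity_feature_names)
}
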