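# Intensity-histogram features (23, on discretized grey levels) and
# intensity-volume-histogram features (7, on fractional intensities).

histogram_feature_names <- c(
  "ih_mean", "ih_var", "ih_skew", "ih_kurt", "ih_median", "ih_min", "ih_p10",
  "ih_p90", "ih_max", "ih_mode", "ih_iqr", "ih_range", "ih_mad", "ih_rmad",
  "ih_medad", "ih_cov", "ih_qcod", "ih_entropy", "ih_uniformity",
  "ih_max_grad", "ih_max_grad_level", "ih_min_grad", "ih_min_grad_level",
  "ivh_v10", "ivh_v90", "ivh_v10_minus_v90", "ivh_i10", "ivh_i90",
  "ivh_i10_minus_i90", "ivh_auc"
)

#' Histogram and intensity-volume-histogram features for one lesion
#'
#' 23 statistics of the discretized grey-level histogram (moments,
#' quantiles, mode, dispersion measures, entropy, uniformity, and the
#' histogram-gradient quartet) plus 7 intensity-volume-histogram features
#' (volume fractions at the 10%/90% intensity fractions, intensities at the
#' 10%/90% volume fractions, their differences, and the area under the IVH
#' curve). A single-level histogram has entropy 0 and uniformity 1.
#'
#' @param lesion a [lesion_image()].
#' @param cfg a [discretize_config()].
#' @return Named numeric vector of length 30.
#' @export
histogram_features <- function(lesion, cfg = discretize_config()) {
  lv <- discretize(lesion, cfg)
  ng <- attr(lv, "n_levels")
  g <- lv[!is.na(lv)]
  n <- length(g)
  cnt <- tabulate(g, nbins = ng)
  p <- cnt / n
  mu <- sum(seq_len(ng) * p)
  v <- sum((seq_len(ng) - mu)^2 * p)
  s <- sqrt(v)
  skew <- if (s > 0) sum((seq_len(ng) - mu)^3 * p) / s^3 else 0
  kurt <- if (s > 0) sum((seq_len(ng) - mu)^4 * p) / s^4 - 3 else 0
  q <- quantile(g, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  iqr <- q[4] - q[2]
  mode_lev <- which.max(cnt)  # smallest level on ties
  rset <- g[g >= q[1] & g <= q[5]]
  rmad <- mean(abs(rset - mean(rset)))
  cov_ <- if (mu != 0 && s > 0) s / mu else 0
  qcod <- if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0
  entropy <- -sum(p[p > 0] * log2(p[p > 0]))
  unif <- sum(p^2)
  # histogram gradient (central differences, one-sided at the edges)
  grad <- if (ng > 1) {
    c(cnt[2] - cnt[1],
      if (ng > 2) (cnt[3:ng] - cnt[1:(ng - 2)]) / 2 else NULL,
      cnt[ng] - cnt[ng - 1])
  } else 0
  # IVH on fractional intensities
  x <- lesion$image[lesion$mask]
  rng <- range(x)
  gam <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else rep(0, n)
  nu <- function(thr) mean(gam >= thr)
  ivh_i <- function(vol_frac) {
    # lowest fractional intensity at which at most vol_frac of the volume remains
    cand <- sort(unique(gam))
    ok <- cand[vapply(cand, nu, numeric(1)) <= vol_frac]
    if (length(ok)) min(ok) else max(cand)
  }
  i10 <- ivh_i(0.10)
  i90 <- ivh_i(0.90)
  setNames(c(
    mu, v, skew, kurt, q[3], min(g), q[1], q[5], max(g), mode_lev, iqr,
    max(g) - min(g), mean(abs(g - mean(g))), rmad, mean(abs(g - q[3])),
    cov_, qcod, entropy, unif,
    max(grad), which.max(grad), min(grad), which.min(grad),
    nu(0.10), nu(0.90), nu(0.10) - nu(0.90), i10, i90, i10 - i90, mean(gam)
  ), histogram_feature_names)
}
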