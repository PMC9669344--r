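#' Grey-level discretization settings
#'
#' Histogram and texture features operate on integer grey levels obtained by
#' binning the raw intensities inside the mask. Two standard schemes are
#' supported: a fixed number of bins spanning the masked intensity range
#' (scale-invariant; the default, 64 bins), or a fixed bin width anchored at
#' the masked minimum.
#'
#' @param method `"fixed_bin_number"` or `"fixed_bin_size"`.
#' @param value bin count (fixed_bin_number) or bin width (fixed_bin_size); > 0.
#' @return A `discretize_config` object.
#' @export
discretize_config <- function(method = c("fixed_bin_number", "fixed_bin_size"),
                              value = 64) {
  method <- match.arg(method)
  value <- as.numeric(value)
  if (length(value) != 1L || !is.finite(value) || value <= 0)
    abort("`value` must be a single positive number")
  if (method == "fixed_bin_number") value <- as.integer(value)
  structure(list(method = method, value = value), class = "discretize_config")
}

#' Discretize a lesion's intensities to integer grey levels
#'
#' Under fixed bin number with `N` bins, masked intensities in `[min, max]`
#' map to levels `floor(N * (x - min) / (max - min)) + 1`, capped at `N`
#' (so the maximum maps to `N`). A constant region maps entirely to level 1.
#' Under fixed bin size `w`, levels are `floor((x - min) / w) + 1`.
#'
#' @param lesion a [lesion_image()].
#' @param cfg a [discretize_config()].
#' @return Integer array congruent with the lesion grid; `NA` outside the
#'   mask, levels `>= 1` inside. The number of grey levels used downstream is
#'   attached as attribute `"n_levels"`.
#' @examples
#' les <- lesion_image(array(c(1, 2, 3, 10, 0, 0, 0, 0), c(2, 2, 2)),
#'                     array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
#' lv <- discretize(les, discretize_config("fixed_bin_number", 2))
#' lv[!is.na(lv)]  # 1 1 1 2
#' @export
discretize <- function(lesion, cfg = discretize_config()) {
  stopifnot(inherits(lesion, "lesion_image"), inherits(cfg, "discretize_config"))
  x <- lesion$image
  m <- lesion$mask
  lv <- array(NA_integer_, dim(x))
  vals <- x[m]
  rng <- range(vals)
  if (cfg$method == "fixed_bin_number") {
    n <- cfg$value
    if (rng[1] == rng[2]) {
      lv[m] <- 1L
    } else {
      lev <- floor(n * (vals - rng[1]) / (rng[2] - rng[1])) + 1
      lv[m] <- as.integer(pmin(lev, n))
    }
    attr(lv, "n_levels") <- as.integer(n)
  } else {
    lev <- floor((vals - rng[1]) / cfg$value) + 1
    lv[m] <- as.integer(lev)
    attr(lv, "n_levels") <- as.integer(max(lev))
  }
  lv
}
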