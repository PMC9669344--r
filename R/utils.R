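#' @keywords internal
"_PACKAGE"

#' @importFrom Rcpp sourceCpp
#' @useDynLib radspat, .registration = TRUE
#' @importFrom rlang %||% abort warn .data
#' @importFrom stats var sd cor quantile median mad rnorm rpois runif setNames
#'   hclust cutree as.dist glm binomial coef predict pnorm fisher.test
#' @importFrom utils head tail
NULL

# Shift a 3D array by an integer offset d = c(dx, dy, dz):
# out[x] = a[x + d], positions falling outside the grid become `fill`.
shift3 <- function(a, d, fill = NA) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    n <- dm[ax]
    if (abs(d[ax]) >= n) return(out)
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(n - d[ax])
      src[[ax]] <- seq_len(n - d[ax]) + d[ax]
    } else {
      dst[[ax]] <- seq_len(n + d[ax]) - d[ax]
      src[[ax]] <- seq_len(n + d[ax])
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 13 unique 3D directions (one per +/- pair), unit Chebyshev distance.
directions_3d <- function() {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(abs(d)) > 0, , drop = FALSE]
  keep <- apply(d, 1, function(v) {
    v[1] > 0 || (v[1] == 0 && v[2] > 0) || (v[1] == 0 && v[2] == 0 && v[3] > 0)
  })
  unname(d[keep, , drop = FALSE])
}

# 4 unique in-plane directions for a given slice axis (default axis 3, axial).
directions_2d <- function(slice_axis = 3L) {
  base <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  out <- matrix(0L, nrow(base), 3L)
  ax <- setdiff(1:3, slice_axis)
  out[, ax[1]] <- base[, 1]
  out[, ax[2]] <- base[, 2]
  out
}

# All 26 (or in-plane 8) neighbour offsets.
neighbour_offsets <- function(dim3d = TRUE, slice_axis = 3L) {
  if (dim3d) {
    d <- directions_3d()
  } else {
    d <- directions_2d(slice_axis)
  }
  rbind(d, -d)
}

# Deterministic 31-bit sub-seed from a master seed and a label path.
derive_seed <- function(seed, ...) {
  labs <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labs)) h <- (h * 131 + ch) %% 2147483629
  as.integer(h)
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Separable Gaussian smoothing of a 3D array; sigma in voxels per axis.
gaussian_smooth3 <- function(a, sigma) {
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim(a))
    wts <- array(0, dim(a))
    for (i in seq_along(k)) {
      off <- c(0L, 0L, 0L)
      off[ax] <- (-r:r)[i]
      sh <- shift3(a, off, fill = NA)
      ok <- !is.na(sh)
      acc[ok] <- acc[ok] + k[i] * sh[ok]
      wts[ok] <- wts[ok] + k[i]
    }
    a <- acc / wts
  }
  a
}

# Crop an array to the bounding box of `mask`, with an optional margin.
# Returns list(index = list of 3 index vectors).
bbox_index <- function(mask, margin = 0L) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) abort("mask is empty")
  dm <- dim(mask)
  lapply(1:3, function(ax) {
    lo <- max(1L, min(w[, ax]) - margin)
    hi <- min(dm[ax], max(w[, ax]) + margin)
    lo:hi
  })
}

# Connected components of a logical 3D array via igraph.
# connectivity: 26 (3D), 6 (3D faces), or 8 (in-plane per slice, slice_axis).
label_components_array <- function(mask, connectivity = 26L, slice_axis = 3L) {
  lab <- array(0L, dim(mask))
  idx <- which(mask)
  if (length(idx) == 0) return(lab)
  offs <- switch(as.character(connectivity),
    "26" = directions_3d(),
    "6"  = rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
    "8"  = directions_2d(slice_axis),
    abort("unsupported connectivity")
  )
  pos <- array(0L, dim(mask))
  pos[idx] <- seq_along(idx)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    sh <- shift3(pos, offs[r, ], fill = 0L)
    a <- pos[idx]
    b <- sh[idx]
    ok <- b > 0L
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(a[ok], b[ok])
  }
  memb <- if (length(edges) == 0) {
    seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    igraph::components(g)$membership
  }
  # relabel components 1..k in order of first appearance
  memb <- match(memb, unique(memb))
  lab[idx] <- memb
  lab
}
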