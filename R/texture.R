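# Higher-order texture features on the discretized grey-level grid.
#
# Six matrix families: co-occurrence (GLCM), run length (GLRLM), size zone
# (GLSZM), distance zone (GLDZM), neighbourhood tone difference (NGTDM) and
# neighbouring grey level dependence (NGLDM). GLCM/GLRLM are computed under
# four aggregations (2D per-slice per-direction averaged, 2D per-slice
# direction-merged, 3D per-direction averaged, 3D direction-merged); the zone
# and neighbourhood families under two (2D per-slice averaged, 3D).
# Distance-1 neighbourhoods (13 unique 3D directions, 4 in-plane) throughout.

texture_agg_glcm <- c("2d_avg", "2d_mrg", "3d_avg", "3d_mrg")
texture_agg_zone <- c("2d", "3d")

glcm_base_names <- c(
  "joint_max", "joint_avg", "joint_var", "joint_entropy",
  "diff_avg", "diff_var", "diff_entropy",
  "sum_avg", "sum_var", "sum_entropy",
  "energy", "contrast", "dissimilarity",
  "inv_diff", "inv_diff_norm", "inv_diff_mom", "inv_diff_mom_norm",
  "inv_var", "corr", "autocorr",
  "clust_tend", "clust_shade", "clust_prom",
  "info_corr1", "info_corr2"
)

glrlm_base_names <- c(
  "sre", "lre", "lgre", "hgre", "srlge", "srhge", "lrlge", "lrhge",
  "glnu", "glnu_norm", "rlnu", "rlnu_norm", "run_pct",
  "gl_var", "rl_var", "run_entropy"
)

glszm_base_names <- c(
  "sze", "lze", "lgze", "hgze", "szlge", "szhge", "lzlge", "lzhge",
  "glnu", "glnu_norm", "zsnu", "zsnu_norm", "zone_pct",
  "gl_var", "zs_var", "zs_entropy"
)

gldzm_base_names <- c(
  "sde", "lde", "lgze", "hgze", "sdlge", "sdhge", "ldlge", "ldhge",
  "glnu", "glnu_norm", "zdnu", "zdnu_norm", "zone_pct",
  "gl_var", "zd_var", "zd_entropy"
)

ngtdm_base_names <- c("coarseness", "contrast", "busyness", "complexity", "strength")

ngldm_base_names <- c(
  "lde", "hde", "lgce", "hgce", "ldlge", "ldhge", "hdlge", "hdhge",
  "glnu", "glnu_norm", "dcnu", "dcnu_norm", "dc_pct",
  "gl_var", "dc_var", "dc_entropy", "dc_energy"
)

# ---- GLCM -------------------------------------------------------------------

# Symmetric co-occurrence count matrix for one direction.
glcm_matrix <- function(lv, ng, d) {
  sh <- shift3(lv, d, fill = NA_integer_)
  ok <- !is.na(lv) & !is.na(sh)
  m <- matrix(0, ng, ng)
  if (any(ok)) {
    a <- lv[ok]
    b <- sh[ok]
    m <- matrix(tabulate((a - 1L) * ng + b, nbins = ng * ng), ng, ng)
  }
  m + t(m)
}

log2p <- function(p) ifelse(p > 0, log2(p), 0)

# The 25 co-occurrence features from a count matrix (any aggregation).
glcm_features <- function(m) {
  ng <- nrow(m)
  p <- m / sum(m)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  pi_m <- rowSums(p)            # marginal (symmetric, so row = col marginal)
  mu <- sum(i * p)
  dvals <- 0:(ng - 1)
  pd <- vapply(dvals, function(k) sum(p[abs(i - j) == k]), numeric(1))
  svals <- 2:(2 * ng)
  ps <- vapply(svals, function(k) sum(p[(i + j) == k]), numeric(1))
  mu_d <- sum(dvals * pd)
  mu_s <- sum(svals * ps)
  sig <- sqrt(sum((i - mu)^2 * p))
  hxy <- -sum(p * log2p(p))
  pipj <- pi_m[i] * pi_m[j]
  hxy1 <- -sum(p * log2p(pipj))
  hxy2 <- -sum(pipj * log2p(pipj))
  hx <- -sum(pi_m * log2p(pi_m))
  ic1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  ic2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  off <- i != j
  setNames(c(
    max(p),
    mu,
    sum((i - mu)^2 * p),
    hxy,
    mu_d,
    sum((dvals - mu_d)^2 * pd),
    -sum(pd * log2p(pd)),
    mu_s,
    sum((svals - mu_s)^2 * ps),
    -sum(ps * log2p(ps)),
    sum(p^2),
    sum((i - j)^2 * p),
    sum(abs(i - j) * p),
    sum(p / (1 + abs(i - j))),
    sum(p / (1 + abs(i - j) / ng)),
    sum(p / (1 + (i - j)^2)),
    sum(p / (1 + (i - j)^2 / ng^2)),
    sum(p[off] / (i[off] - j[off])^2),
    if (sig > 0) (sum(i * j * p) - mu^2) / sig^2 else 0,
    sum(i * j * p),
    sum((i + j - 2 * mu)^2 * p),
    sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    ic1,
    ic2
  ), glcm_base_names)
}

# Degenerate fallback: a single self-pair at the modal grey level.
degenerate_pair_matrix <- function(lv, ng) {
  lev <- which.max(tabulate(lv[!is.na(lv)], nbins = ng))
  m <- matrix(0, ng, ng)
  m[lev, lev] <- 2
  m
}

slice_indices <- function(lv) {
  which(apply(!is.na(lv), 3, any))
}

average_feature_rows <- function(rows, names, fallback) {
  if (length(rows) == 0) return(setNames(fallback, names))
  rowMeans(do.call(cbind, rows))
}

glcm_all <- function(lv, ng) {
  out <- numeric(0)
  d2 <- directions_2d(3L)
  d3 <- directions_3d()
  slices <- slice_indices(lv)
  per_sd <- list()   # matrices by slice then direction
  for (k in slices) {
    sl <- lv[, , k, drop = FALSE]
    per_sd[[as.character(k)]] <- lapply(seq_len(nrow(d2)), function(r)
      glcm_matrix(sl, ng, d2[r, ]))
  }
  nonempty <- function(ms) ms[vapply(ms, sum, numeric(1)) > 0]
  fallback_feats <- glcm_features(degenerate_pair_matrix(lv, ng))
  # 2d_avg: features per slice x direction, averaged
  ms <- nonempty(unlist(per_sd, recursive = FALSE))
  f <- if (length(ms)) average_feature_rows(lapply(ms, glcm_features), glcm_base_names, NULL) else fallback_feats
  out <- c(out, setNames(f, paste0("glcm_", glcm_base_names, "_2d_avg")))
  # 2d_mrg: directions merged per slice, features averaged over slices
  ms <- nonempty(lapply(per_sd, function(l) Reduce(`+`, l)))
  f <- if (length(ms)) average_feature_rows(lapply(ms, glcm_features), glcm_base_names, NULL) else fallback_feats
  out <- c(out, setNames(f, paste0("glcm_", glcm_base_names, "_2d_mrg")))
  # 3d_avg / 3d_mrg
  m3 <- lapply(seq_len(nrow(d3)), function(r) glcm_matrix(lv, ng, d3[r, ]))
  ms <- nonempty(m3)
  f <- if (length(ms)) average_feature_rows(lapply(ms, glcm_features), glcm_base_names, NULL) else fallback_feats
  out <- c(out, setNames(f, paste0("glcm_", glcm_base_names, "_3d_avg")))
  mm <- Reduce(`+`, m3)
  f <- if (sum(mm) > 0) glcm_features(mm) else fallback_feats
  out <- c(out, setNames(f, paste0("glcm_", glcm_base_names, "_3d_mrg")))
  out
}

# ---- shared size-zone style feature block -----------------------------------

# Generic features for matrices whose rows are grey levels and whose second
# index j carries run length / zone size / zone distance / dependence count.
# `m` is a counts matrix with columns indexed by `js`; `nv` the voxel count
# entering the percentage feature.
sizezone_features <- function(m, js, nv, energy = FALSE) {
  ns <- sum(m)
  if (ns == 0) {
    k <- if (energy) 17L else 16L
    return(numeric(k))
  }
  ng <- nrow(m)
  iv <- matrix(seq_len(ng), ng, length(js))
  jv <- matrix(js, ng, length(js), byrow = TRUE)
  ri <- rowSums(m)
  cj <- colSums(m)
  p <- m / ns
  mu_i <- sum(iv * p)
  mu_j <- sum(jv * p)
  base <- c(
    sum(m / jv^2) / ns,
    sum(m * jv^2) / ns,
    sum(m / iv^2) / ns,
    sum(m * iv^2) / ns,
    sum(m / (iv^2 * jv^2)) / ns,
    sum(m * iv^2 / jv^2) / ns,
    sum(m * jv^2 / iv^2) / ns,
    sum(m * iv^2 * jv^2) / ns,
    sum(ri^2) / ns,
    sum(ri^2) / ns^2,
    sum(cj^2) / ns,
    sum(cj^2) / ns^2,
    ns / nv,
    sum(p * (iv - mu_i)^2),
    sum(p * (jv - mu_j)^2),
    -sum(p * log2p(p))
  )
  if (energy) base <- c(base, sum(p^2))
  base
}

# ---- GLRLM ------------------------------------------------------------------

# Run starts/lengths along direction d. Returns data frame (level, len, slice).
run_lengths <- function(lv, d) {
  mask <- !is.na(lv)
  nx <- shift3(lv, d, fill = NA_integer_)
  same_next <- mask & !is.na(nx) & lv == nx           # same level at v + d
  R <- array(0, dim(lv))
  R[mask] <- 1
  maxit <- sum(dim(lv))
  for (it in seq_len(maxit)) {
    S <- shift3(R, d, fill = 0)
    Rn <- array(0, dim(lv))
    Rn[mask] <- 1
    Rn[same_next] <- 1 + S[same_next]
    if (identical(Rn, R)) break
    R <- Rn
  }
  same_prev <- shift3(same_next, -d, fill = FALSE)
  same_prev[is.na(same_prev)] <- FALSE
  start <- mask & !same_prev
  w <- which(start, arr.ind = TRUE)
  data.frame(level = lv[start], len = R[start], slice = w[, 3])
}

rlm_counts <- function(runs, ng, maxlen) {
  m <- matrix(0, ng, maxlen)
  if (nrow(runs)) {
    t <- tapply(rep(1, nrow(runs)), list(factor(runs$level, levels = seq_len(ng)),
                                         factor(runs$len, levels = seq_len(maxlen))), sum)
    t[is.na(t)] <- 0
    m <- unclass(t)
  }
  m
}

glrlm_all <- function(lv, ng) {
  out <- numeric(0)
  maxlen <- max(dim(lv))
  nv_total <- sum(!is.na(lv))
  nv_slice <- apply(!is.na(lv), 3, sum)
  d2 <- directions_2d(3L)
  d3 <- directions_3d()
  runs2 <- lapply(seq_len(nrow(d2)), function(r) run_lengths(lv, d2[r, ]))
  feats <- function(runs, nv) sizezone_features(rlm_counts(runs, ng, maxlen), seq_len(maxlen), nv)
  slices <- slice_indices(lv)
  # 2d_avg: per slice x direction
  rows <- list()
  for (k in slices) for (r in seq_along(runs2)) {
    rs <- runs2[[r]][runs2[[r]]$slice == k, , drop = FALSE]
    if (nrow(rs)) rows[[length(rows) + 1L]] <- feats(rs, nv_slice[k])
  }
  out <- c(out, setNames(average_feature_rows(rows, glrlm_base_names, numeric(16)),
                         paste0("glrlm_", glrlm_base_names, "_2d_avg")))
  # 2d_mrg: directions merged within slice
  rows <- list()
  for (k in slices) {
    rs <- do.call(rbind, lapply(runs2, function(x) x[x$slice == k, , drop = FALSE]))
    if (nrow(rs)) rows[[length(rows) + 1L]] <- feats(rs, nv_slice[k])
  }
  out <- c(out, setNames(average_feature_rows(rows, glrlm_base_names, numeric(16)),
                         paste0("glrlm_", glrlm_base_names, "_2d_mrg")))
  # 3d
  runs3 <- lapply(seq_len(nrow(d3)), function(r) run_lengths(lv, d3[r, ]))
  rows <- lapply(runs3, feats, nv = nv_total)
  out <- c(out, setNames(average_feature_rows(rows, glrlm_base_names, numeric(16)),
                         paste0("glrlm_", glrlm_base_names, "_3d_avg")))
  f <- feats(do.call(rbind, runs3), nv_total)
  out <- c(out, setNames(f, paste0("glrlm_", glrlm_base_names, "_3d_mrg")))
  out
}

# ---- zones (GLSZM / GLDZM) --------------------------------------------------

# Connected zones of equal grey level. dim3d: 26-connectivity; otherwise
# 8-connectivity within axial slices (so zones never span slices).
zone_table <- function(lv, dim3d = TRUE) {
  mask <- !is.na(lv)
  idx <- which(mask)
  pos <- array(0L, dim(lv))
  pos[idx] <- seq_along(idx)
  offs <- if (dim3d) directions_3d() else directions_2d(3L)
  edges <- list()
  for (r in seq_len(nrow(offs))) {
    shp <- shift3(pos, offs[r, ], fill = 0L)
    shl <- shift3(lv, offs[r, ], fill = NA_integer_)
    ok <- mask & shp > 0L & !is.na(shl) & lv == shl
    ok[is.na(ok)] <- FALSE
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(pos[ok], shp[ok])
  }
  memb <- if (length(edges) == 0) {
    seq_along(idx)
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    igraph::components(g)$membership
  }
  memb <- match(memb, unique(memb))
  w <- which(mask, arr.ind = TRUE)
  data.frame(
    zone = memb, level = lv[idx], slice = w[, 3],
    idx = idx
  )
}

# City-block distance (6-connectivity steps; in-plane 4-connectivity for 2D)
# from each ROI voxel to the nearest voxel outside the ROI; border voxels 1.
roi_distance_map <- function(mask, dim3d = TRUE) {
  d <- array(0, dim(mask))
  d[mask] <- Inf
  offs <- if (dim3d) rbind(diag(3), -diag(3)) else {
    o <- matrix(0L, 4, 3); o[1:2, 1] <- c(1, -1); o[3:4, 2] <- c(1, -1); o
  }
  repeat {
    dn <- d
    for (r in seq_len(nrow(offs))) {
      dn <- pmin(dn, shift3(d, offs[r, ], fill = 0) + 1)
    }
    dn[!mask] <- 0
    if (identical(dn, d)) break
    d <- dn
  }
  d
}

zone_summary <- function(zt, distmap = NULL) {
  sz <- tapply(rep(1, nrow(zt)), zt$zone, sum)
  lev <- tapply(zt$level, zt$zone, function(x) x[1])
  sl <- tapply(zt$slice, zt$zone, function(x) x[1])
  out <- data.frame(level = as.vector(lev), size = as.vector(sz), slice = as.vector(sl))
  if (!is.null(distmap)) out$dist <- as.vector(tapply(distmap[zt$idx], zt$zone, min))
  out
}

zone_counts <- function(zs, ng, col, maxj) {
  m <- matrix(0, ng, maxj)
  if (nrow(zs)) {
    t <- tapply(rep(1, nrow(zs)), list(factor(zs$level, levels = seq_len(ng)),
                                       factor(zs[[col]], levels = seq_len(maxj))), sum)
    t[is.na(t)] <- 0
    m <- unclass(t)
  }
  m
}

glszm_gldzm_all <- function(lv, ng) {
  out <- numeric(0)
  nv_total <- sum(!is.na(lv))
  nv_slice <- apply(!is.na(lv), 3, sum)
  for (fam in c("glszm", "gldzm")) {
    bn <- if (fam == "glszm") glszm_base_names else gldzm_base_names
    for (agg in texture_agg_zone) {
      dim3d <- agg == "3d"
      zt <- zone_table(lv, dim3d = dim3d)
      dm <- if (fam == "gldzm") roi_distance_map(!is.na(lv), dim3d = dim3d) else NULL
      zs <- zone_summary(zt, distmap = dm)
      col <- if (fam == "glszm") "size" else "dist"
      maxj <- max(zs[[col]], 1)
      if (dim3d) {
        f <- sizezone_features(zone_counts(zs, ng, col, maxj), seq_len(maxj), nv_total)
      } else {
        rows <- lapply(unique(zs$slice), function(k)
          sizezone_features(zone_counts(zs[zs$slice == k, , drop = FALSE], ng, col, maxj),
                            seq_len(maxj), nv_slice[k]))
        f <- average_feature_rows(rows, bn, numeric(16))
      }
      out <- c(out, setNames(f, paste0(fam, "_", bn, "_", agg)))
    }
  }
  out
}

# ---- NGTDM ------------------------------------------------------------------

# Per-voxel mean of valid neighbour levels; returns per-voxel data.
neighbour_mean <- function(lv, dim3d = TRUE) {
  offs <- neighbour_offsets(dim3d)
  acc <- array(0, dim(lv))
  cnt <- array(0, dim(lv))
  for (r in seq_len(nrow(offs))) {
    s <- shift3(lv, offs[r, ], fill = NA_integer_)
    ok <- !is.na(s)
    acc[ok] <- acc[ok] + s[ok]
    cnt[ok] <- cnt[ok] + 1
  }
  mask <- !is.na(lv)
  valid <- mask & cnt > 0
  w <- which(valid, arr.ind = TRUE)
  data.frame(level = lv[valid], dev = abs(lv[valid] - acc[valid] / cnt[valid]),
             slice = w[, 3])
}

ngtdm_features_from <- function(level, dev, ng) {
  nv <- length(level)
  if (nv == 0) return(numeric(5))
  n_i <- tabulate(level, nbins = ng)
  s_i <- numeric(ng)
  agg <- tapply(dev, level, sum)
  s_i[as.integer(names(agg))] <- agg
  p_i <- n_i / nv
  present <- which(p_i > 0)
  ngp <- length(present)
  ps <- sum(p_i * s_i)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  contrast <- 0
  busyness <- 0
  complexity <- 0
  strength <- 0
  if (ngp > 1) {
    iv <- matrix(present, ngp, ngp)
    jv <- t(iv)
    pi_ <- p_i[present]
    pim <- matrix(pi_, ngp, ngp)
    pjm <- t(pim)
    contrast <- sum(pim * pjm * (iv - jv)^2) / (ngp * (ngp - 1)) * sum(s_i) / nv
    den <- sum(abs(iv * pim - jv * pjm)[iv != jv])
    busyness <- if (den > 0) ps / den else 0
    si_m <- matrix(s_i[present], ngp, ngp)
    sj_m <- t(si_m)
    off <- iv != jv
    complexity <- sum((abs(iv - jv) * (pim * si_m + pjm * sj_m) / (pim + pjm))[off]) / nv
    ss <- sum(s_i)
    strength <- if (ss > 0) sum(((pim + pjm) * (iv - jv)^2)[off]) / ss else 0
  }
  c(coarseness, contrast, busyness, complexity, strength)
}

ngtdm_all <- function(lv, ng) {
  out <- numeric(0)
  for (agg in texture_agg_zone) {
    nb <- neighbour_mean(lv, dim3d = agg == "3d")
    if (agg == "3d") {
      f <- ngtdm_features_from(nb$level, nb$dev, ng)
    } else {
      rows <- lapply(unique(nb$slice), function(k) {
        sub <- nb[nb$slice == k, , drop = FALSE]
        ngtdm_features_from(sub$level, sub$dev, ng)
      })
      f <- average_feature_rows(rows, ngtdm_base_names, numeric(5))
    }
    out <- c(out, setNames(f, paste0("ngtdm_", ngtdm_base_names, "_", agg)))
  }
  out
}

# ---- NGLDM ------------------------------------------------------------------

# Dependence count: number of neighbours (Chebyshev distance 1) inside the
# mask with identical grey level (coarseness parameter 0). The dependence
# value used in the feature formulas is count + 1 (the voxel itself).
ngldm_table <- function(lv, dim3d = TRUE) {
  offs <- neighbour_offsets(dim3d)
  cnt <- array(0L, dim(lv))
  for (r in seq_len(nrow(offs))) {
    s <- shift3(lv, offs[r, ], fill = NA_integer_)
    same <- !is.na(lv) & !is.na(s) & lv == s
    same[is.na(same)] <- FALSE
    cnt[same] <- cnt[same] + 1L
  }
  mask <- !is.na(lv)
  w <- which(mask, arr.ind = TRUE)
  data.frame(level = lv[mask], dep = cnt[mask] + 1L, slice = w[, 3])
}

ngldm_all <- function(lv, ng) {
  out <- numeric(0)
  for (agg in texture_agg_zone) {
    dim3d <- agg == "3d"
    tb <- ngldm_table(lv, dim3d = dim3d)
    maxdep <- max(tb$dep)
    counts <- function(sub) {
      t <- tapply(rep(1, nrow(sub)), list(factor(sub$level, levels = seq_len(ng)),
                                          factor(sub$dep, levels = seq_len(maxdep))), sum)
      t[is.na(t)] <- 0
      unclass(t)
    }
    if (dim3d) {
      f <- sizezone_features(counts(tb), seq_len(maxdep), nrow(tb), energy = TRUE)
    } else {
      rows <- lapply(unique(tb$slice), function(k) {
        sub <- tb[tb$slice == k, , drop = FALSE]
        sizezone_features(counts(sub), seq_len(maxdep), nrow(sub), energy = TRUE)
      })
      f <- average_feature_rows(rows, ngldm_base_names, numeric(17))
    }
    out <- c(out, setNames(f, paste0("ngldm_", ngldm_base_names, "_", agg)))
  }
  out
}

# ---- entry point ------------------------------------------------------------

#' Higher-order texture features for one lesion
#'
#' Computes the 272 texture features: 25 co-occurrence features under 4
#' aggregations, 16 run-length features under 4 aggregations, 16 size-zone and
#' 16 distance-zone features under 2 aggregations, 5 neighbourhood
#' tone-difference and 17 grey-level dependence features under 2 aggregations.
#' Matrices use distance-1 neighbourhoods; 2D aggregations use axial slices
#' (the third array axis by default).
#'
#' @param lesion a [lesion_image()].
#' @param cfg a [discretize_config()].
#' @param slice_axis array axis treated as the slice (acquisition) axis.
#' @return Named numeric vector of length 272.
#' @export
texture_features <- function(lesion, cfg = discretize_config(), slice_axis = 3L) {
  ix <- bbox_index(lesion$mask)
  img <- lesion$image[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  msk <- lesion$mask[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
  sub <- lesion_image(img, msk, lesion$spacing)
  lv <- discretize(sub, cfg)
  ng <- attr(lv, "n_levels")
  if (slice_axis != 3L) {
    perm <- c(setdiff(1:3, slice_axis), slice_axis)
    lv <- aperm(lv, perm)
  }
  c(glcm_all(lv, ng), glrlm_all(lv, ng), glszm_gldzm_all(lv, ng),
    ngtdm_all(lv, ng), ngldm_all(lv, ng))
}
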