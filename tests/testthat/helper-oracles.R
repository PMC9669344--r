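# Independent brute-force oracles: explicit loops, no shared code with the
# package's vectorized builders.

# --- random discretized grids ------------------------------------------------

random_level_grid <- function(dims, ng, p_mask = 0.8) {
  lv <- array(sample.int(ng, prod(dims), replace = TRUE), dims)
  m <- array(runif(prod(dims)) < p_mask, dims)
  if (!any(m)) m[1] <- TRUE
  lv[!m] <- NA_integer_
  lv
}

random_lesion <- function(dims = c(7, 6, 5), spacing = c(1, 1, 1), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  img <- array(rnorm(prod(dims), 50, 12), dims)
  ctr <- (dims + 1) / 2
  g <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])))
  d <- sqrt(rowSums(sweep(g, 2, ctr)^2))
  msk <- array(d <= min(dims) / 2 + runif(nrow(g), -0.8, 0.8), dims)
  if (sum(msk) < 8) msk[ctr[1] + (-1:1), ctr[2] + (-1:1), ctr[3]] <- TRUE
  lesion_image(img, msk, spacing)
}

# --- GLCM oracle -------------------------------------------------------------

oracle_glcm_matrix <- function(lv, ng, d) {
  dm <- dim(lv)
  m <- matrix(0, ng, ng)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    a <- lv[i, j, k]
    if (is.na(a)) next
    ii <- i + d[1]; jj <- j + d[2]; kk <- k + d[3]
    if (ii < 1 || ii > dm[1] || jj < 1 || jj > dm[2] || kk < 1 || kk > dm[3]) next
    b <- lv[ii, jj, kk]
    if (is.na(b)) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

# Naive double-loop GLCM features (same 25 definitions, independent code).
oracle_glcm_features <- function(m) {
  ng <- nrow(m)
  p <- m / sum(m)
  pr <- rowSums(p)
  mu <- 0
  for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  acc <- setNames(numeric(25), radspat:::glcm_base_names)
  pd <- numeric(ng)          # |i-j| = 0..ng-1
  ps <- numeric(2 * ng - 1)  # i+j = 2..2ng
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    ps[i + j - 1] <- ps[i + j - 1] + p[i, j]
  }
  mu_d <- sum((0:(ng - 1)) * pd)
  mu_s <- sum((2:(2 * ng)) * ps)
  sig2 <- 0
  for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  hxy <- hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (p[i, j] > 0) hxy <- hxy - p[i, j] * log2(p[i, j])
    q <- pr[i] * pr[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  hx <- -sum(pr[pr > 0] * log2(pr[pr > 0]))
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    acc["joint_avg"] <- acc["joint_avg"] + i * pij
    acc["joint_var"] <- acc["joint_var"] + (i - mu)^2 * pij
    acc["energy"] <- acc["energy"] + pij^2
    acc["contrast"] <- acc["contrast"] + (i - j)^2 * pij
    acc["dissimilarity"] <- acc["dissimilarity"] + abs(i - j) * pij
    acc["inv_diff"] <- acc["inv_diff"] + pij / (1 + abs(i - j))
    acc["inv_diff_norm"] <- acc["inv_diff_norm"] + pij / (1 + abs(i - j) / ng)
    acc["inv_diff_mom"] <- acc["inv_diff_mom"] + pij / (1 + (i - j)^2)
    acc["inv_diff_mom_norm"] <- acc["inv_diff_mom_norm"] + pij / (1 + (i - j)^2 / ng^2)
    if (i != j) acc["inv_var"] <- acc["inv_var"] + pij / (i - j)^2
    acc["autocorr"] <- acc["autocorr"] + i * j * pij
    acc["clust_tend"] <- acc["clust_tend"] + (i + j - 2 * mu)^2 * pij
    acc["clust_shade"] <- acc["clust_shade"] + (i + j - 2 * mu)^3 * pij
    acc["clust_prom"] <- acc["clust_prom"] + (i + j - 2 * mu)^4 * pij
  }
  acc["joint_max"] <- max(p)
  acc["joint_entropy"] <- hxy
  acc["diff_avg"] <- mu_d
  acc["diff_var"] <- sum(((0:(ng - 1)) - mu_d)^2 * pd)
  acc["diff_entropy"] <- -sum(pd[pd > 0] * log2(pd[pd > 0]))
  acc["sum_avg"] <- mu_s
  acc["sum_var"] <- sum(((2:(2 * ng)) - mu_s)^2 * ps)
  acc["sum_entropy"] <- -sum(ps[ps > 0] * log2(ps[ps > 0]))
  acc["corr"] <- if (sig2 > 0) (acc["autocorr"] - mu^2) / sig2 else 0
  acc["info_corr1"] <- if (hx > 0) (hxy - hxy1) / hx else 0
  acc["info_corr2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  acc
}

# --- GLRLM oracle ------------------------------------------------------------

oracle_runs <- function(lv, d) {
  dm <- dim(lv)
  runs <- NULL
  inb <- function(v) all(v >= 1) && all(v <= dm)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    v <- c(i, j, k)
    a <- lv[i, j, k]
    if (is.na(a)) next
    pv <- v - d
    if (inb(pv) && !is.na(lv[pv[1], pv[2], pv[3]]) &&
        lv[pv[1], pv[2], pv[3]] == a) next  # not a run start
    len <- 1
    nv <- v + d
    while (inb(nv) && !is.na(lv[nv[1], nv[2], nv[3]]) &&
           lv[nv[1], nv[2], nv[3]] == a) {
      len <- len + 1
      nv <- nv + d
    }
    runs <- rbind(runs, c(a, len))
  }
  runs
}

oracle_rlm_matrix <- function(lv, ng, d, maxlen) {
  m <- matrix(0, ng, maxlen)
  runs <- oracle_runs(lv, d)
  if (!is.null(runs)) {
    for (r in seq_len(nrow(runs))) m[runs[r, 1], runs[r, 2]] <- m[runs[r, 1], runs[r, 2]] + 1
  }
  m
}

# --- GLSZM oracle (BFS flood fill, 26- or in-plane 8-connectivity) ----------

oracle_zones <- function(lv, dim3d = TRUE) {
  dm <- dim(lv)
  offs <- as.matrix(expand.grid(-1:1, -1:1, if (dim3d) -1:1 else 0))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  seen <- array(FALSE, dm)
  zones <- NULL
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    if (is.na(lv[i, j, k]) || seen[i, j, k]) next
    lev <- lv[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      size <- size + 1
      for (r in seq_len(nrow(offs))) {
        nv <- v + offs[r, ]
        if (any(nv < 1) || any(nv > dm)) next
        if (seen[nv[1], nv[2], nv[3]]) next
        x <- lv[nv[1], nv[2], nv[3]]
        if (!is.na(x) && x == lev) {
          seen[nv[1], nv[2], nv[3]] <- TRUE
          queue[[length(queue) + 1]] <- nv
        }
      }
    }
    zones <- rbind(zones, c(lev, size))
  }
  zones
}

oracle_szm_matrix <- function(lv, ng, dim3d = TRUE) {
  z <- oracle_zones(lv, dim3d)
  maxs <- max(z[, 2])
  m <- matrix(0, ng, maxs)
  for (r in seq_len(nrow(z))) m[z[r, 1], z[r, 2]] <- m[z[r, 1], z[r, 2]] + 1
  m
}

# --- RIS oracle: literal transcription of the piecewise expression -----------

oracle_ris <- function(rils, t) {
  pos <- c(); neg <- c()
  for (r in rils) {
    if (r >= t) pos <- c(pos, r) else neg <- c(neg, r)
  }
  dpos <- 0; for (r in pos) dpos <- dpos + abs(r - t)
  dneg <- 0; for (r in neg) dneg <- dneg + abs(r - t)
  if (dpos >= dneg) sum(pos) / length(pos) else sum(neg) / length(neg)
}

# --- Youden oracle: exhaustive search over a dense cutoff set ----------------

oracle_youden_j <- function(scores, y) {
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, u - 1e-9, u + 1e-9,
                        (head(u, -1) + tail(u, -1)) / 2)))
  best <- -Inf
  for (t in cand) {
    sens <- mean(scores[y == 1] >= t)
    spec <- mean(scores[y == 0] < t)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Internal accessors used across texture tests.
pkg_glcm_matrix <- radspat:::glcm_matrix
pkg_glcm_features <- radspat:::glcm_features
pkg_rlm_counts <- function(lv, ng, d, maxlen) {
  radspat:::rlm_counts(radspat:::run_lengths(lv, d), ng, maxlen)
}
pkg_szm_matrix <- function(lv, ng, dim3d = TRUE) {
  zs <- radspat:::zone_summary(radspat:::zone_table(lv, dim3d))
  radspat:::zone_counts(zs, ng, "size", max(zs$size))
}
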