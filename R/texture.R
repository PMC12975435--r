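# Gray-level texture matrices and their scalar features.
#
# Conventions shared by all classes:
#  - input is the cropped integer-level array from discretize_region()
#    (NA outside the mask), levels 1..Ng;
#  - 3D geometry: distance-1 offsets, 13 unique directions (26-neighbourhood
#    up to sign) for GLCM/GLRLM, full 26-neighbourhood for GLDM/NGTDM and for
#    GLSZM zone connectivity;
#  - per-direction feature values are averaged over directions;
#  - entropies use log2 with a machine-epsilon guard;
#  - degenerate regions (too few voxels for a matrix) return 0 for every
#    feature of that class, with a warning.

TEXTURE_EPS <- .Machine$double.eps

# 13 unique direction offsets (one representative per +/- pair)
unique_directions_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- apply(g, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  g[keep, , drop = FALSE]
}

# all 26 neighbour offsets
all_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# index ranges of the source block for a shift `off` along each axis;
# NULL when the shifted block is empty (axis shorter than the shift)
shift_ranges <- function(d, off) {
  out <- vector("list", 3)
  for (a in 1:3) {
    lo <- max(1, 1 - off[a])
    hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(NULL)
    out[[a]] <- lo:hi
  }
  out
}

# paired level vectors (a, b) for one offset over a level array with NAs
offset_pairs <- function(lev, off) {
  d <- dim(lev)
  rg <- shift_ranges(d, off)
  if (is.null(rg)) return(list(a = integer(0), b = integer(0)))
  xr <- rg[[1]]; yr <- rg[[2]]; zr <- rg[[3]]
  a <- lev[xr, yr, zr]
  b <- lev[xr + off[1], yr + off[2], zr + off[3]]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

GLCM_FEATURES <- c("Autocorrelation", "JointAverage", "ClusterProminence",
                   "ClusterShade", "ClusterTendency", "Contrast",
                   "Correlation", "DifferenceAverage", "DifferenceEntropy",
                   "DifferenceVariance", "JointEnergy", "JointEntropy",
                   "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn",
                   "InverseVariance", "MaximumProbability", "SumAverage",
                   "SumEntropy", "SumSquares", "MCC")

glcm_features_single <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  k_diff <- abs(i - j)
  pxmy <- vapply(0:(ng - 1), function(k) sum(P[k_diff == k]), numeric(1))
  k_sum <- i + j
  pxpy <- vapply(2:(2 * ng), function(k) sum(P[k_sum == k]), numeric(1))
  da <- sum((0:(ng - 1)) * pxmy)
  hxy <- -sum(P * log2(P + TEXTURE_EPS))
  pxy_prod <- outer(px, py)
  hxy1 <- -sum(P * log2(pxy_prod + TEXTURE_EPS))
  hxy2 <- -sum(pxy_prod * log2(pxy_prod + TEXTURE_EPS))
  hx <- -sum(px * log2(px + TEXTURE_EPS))
  hy <- -sum(py * log2(py + TEXTURE_EPS))
  corr <- if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  # sub-1e-12 arguments are cancellation noise around an exactly
  # independent P (true value 0); the sqrt would blow them up to ~1e-8
  u2 <- max(0, 1 - exp(-2 * (hxy2 - hxy)))
  imc2 <- if (u2 < 1e-12) 0 else sqrt(u2)
  mcc <- {
    keep <- px > 0
    if (sum(keep) <= 1) 1 else {
      Pk <- P[keep, keep, drop = FALSE]
      pxk <- px[keep]; pyk <- py[keep]
      # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
      Q <- matrix(0, nrow(Pk), nrow(Pk))
      for (kk in seq_len(ncol(Pk)))
        if (pyk[kk] > 0)
          Q <- Q + outer(Pk[, kk] / pxk, Pk[, kk]) / pyk[kk]
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      # same guard: a rank-1 Q has second eigenvalue 0 up to round-off
      if (ev[2] < 1e-12) 0 else sqrt(ev[2])
    }
  }
  c(Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy * log2(pxmy + TEXTURE_EPS)),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pxmy),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = imc1,
    Imc2 = imc2,
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(P),
    SumAverage = sum((2:(2 * ng)) * pxpy),
    SumEntropy = -sum(pxpy * log2(pxpy + TEXTURE_EPS)),
    SumSquares = sum((i - mux)^2 * P),
    MCC = mcc)
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetric co-occurrence counts at distance 1 over the 13 unique 3D
#' directions; the 24 scalar features are computed per direction and
#' averaged. `ClusterProminence` is
#' `sum_ij p(i,j) (i + j - mu_x - mu_y)^4`.
#'
#' @param region output of `discretize_region()`, or any list with integer
#'   `levels` array (NA outside the mask) and `n_levels`.
#' @param directions integer matrix of offsets (rows), default all 13.
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(region, directions = unique_directions_3d()) {
  lev <- region$levels
  ng <- region$n_levels
  if (sum(!is.na(lev)) < 2) {
    warning("fewer than 2 voxels: GLCM features set to 0")
    return(stats::setNames(numeric(length(GLCM_FEATURES)), GLCM_FEATURES))
  }
  acc <- NULL
  nd <- 0L
  for (r in seq_len(nrow(directions))) {
    pr <- offset_pairs(lev, directions[r, ])
    if (length(pr$a) == 0) next
    cnt <- matrix(0, ng, ng)
    tab <- tabulate((pr$a - 1L) * ng + pr$b, nbins = ng * ng)
    cnt <- matrix(tab, ng, ng, byrow = TRUE)
    cnt <- cnt + t(cnt)  # symmetric
    P <- cnt / sum(cnt)
    f <- glcm_features_single(P)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) {
    warning("no co-occurring pairs: GLCM features set to 0")
    return(stats::setNames(numeric(length(GLCM_FEATURES)), GLCM_FEATURES))
  }
  acc / nd
}

GLRLM_FEATURES <- c("ShortRunEmphasis", "LongRunEmphasis",
                    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "RunLengthNonUniformity", "RunLengthNonUniformityNormalized",
                    "RunPercentage", "GrayLevelVariance", "RunVariance",
                    "RunEntropy", "LowGrayLevelRunEmphasis",
                    "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
                    "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
                    "LongRunHighGrayLevelEmphasis")

# run-length matrix for one direction: rows = gray level, cols = run length
glrlm_matrix <- function(lev, off) {
  d <- dim(lev)
  maxlen <- max(d)
  # line starts: voxels whose predecessor along `off` is outside the grid
  coords <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                  z = seq_len(d[3])))
  pred <- sweep(coords, 2, off)
  outside <- pred[, 1] < 1 | pred[, 1] > d[1] |
    pred[, 2] < 1 | pred[, 2] > d[2] |
    pred[, 3] < 1 | pred[, 3] > d[3]
  starts <- coords[outside, , drop = FALSE]
  nl <- nrow(starts)
  seqs <- matrix(NA_integer_, nl, maxlen)
  pos <- starts
  for (t in seq_len(maxlen)) {
    ok <- pos[, 1] >= 1 & pos[, 1] <= d[1] &
      pos[, 2] >= 1 & pos[, 2] <= d[2] &
      pos[, 3] >= 1 & pos[, 3] <= d[3]
    if (!any(ok)) break
    lin <- (pos[ok, 3] - 1L) * d[1] * d[2] + (pos[ok, 2] - 1L) * d[1] + pos[ok, 1]
    seqs[which(ok), t] <- lev[lin]
    pos <- sweep(pos, 2, off, "+")
  }
  ng <- max(lev, na.rm = TRUE)
  R <- matrix(0, ng, maxlen)
  for (li in seq_len(nl)) {
    v <- seqs[li, ]
    v[is.na(v)] <- 0L
    r <- rle(v)
    keep <- r$values > 0
    if (any(keep)) {
      for (k in which(keep))
        R[r$values[k], r$lengths[k]] <- R[r$values[k], r$lengths[k]] + 1
    }
  }
  R
}

glrlm_features_single <- function(R, n_voxels) {
  nr <- sum(R)
  p <- R / nr
  i <- row(R); l <- col(R)
  ri <- rowSums(R); rl <- colSums(R)
  mu_i <- sum(p * i); mu_l <- sum(p * l)
  c(ShortRunEmphasis = sum(p / l^2),
    LongRunEmphasis = sum(p * l^2),
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    RunLengthNonUniformity = sum(rl^2) / nr,
    RunLengthNonUniformityNormalized = sum(rl^2) / nr^2,
    RunPercentage = nr / n_voxels,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    RunVariance = sum(p * (l - mu_l)^2),
    RunEntropy = -sum(p * log2(p + TEXTURE_EPS)),
    LowGrayLevelRunEmphasis = sum(p / i^2),
    HighGrayLevelRunEmphasis = sum(p * i^2),
    ShortRunLowGrayLevelEmphasis = sum(p / (i^2 * l^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * i^2 / l^2),
    LongRunLowGrayLevelEmphasis = sum(p * l^2 / i^2),
    LongRunHighGrayLevelEmphasis = sum(p * i^2 * l^2))
}

#' Gray-level run-length matrix features
#'
#' Maximal runs of equal gray level along each of the 13 unique directions;
#' out-of-mask voxels break runs. The 16 features are averaged over
#' directions. `GrayLevelVariance` is `sum_il p(i,l) (i - mu)^2` with
#' `mu = sum_il p(i,l) i`.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(region, directions = unique_directions_3d()) {
  lev <- region$levels
  nv <- sum(!is.na(lev))
  if (nv < 1) {
    warning("empty region: GLRLM features set to 0")
    return(stats::setNames(numeric(length(GLRLM_FEATURES)), GLRLM_FEATURES))
  }
  acc <- NULL
  for (r in seq_len(nrow(directions))) {
    R <- glrlm_matrix(lev, directions[r, ])
    f <- glrlm_features_single(R, nv)
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(directions)
}

GLSZM_FEATURES <- c("SmallAreaEmphasis", "LargeAreaEmphasis",
                    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                    "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                    "ZonePercentage", "GrayLevelVariance", "ZoneVariance",
                    "ZoneEntropy", "LowGrayLevelZoneEmphasis",
                    "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
                    "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
                    "LargeAreaHighGrayLevelEmphasis")

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level; the matrix counts
#' zones by level and size (direction-free).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(region) {
  lev <- region$levels
  ng <- region$n_levels
  nv <- sum(!is.na(lev))
  if (nv < 1) {
    warning("empty region: GLSZM features set to 0")
    return(stats::setNames(numeric(length(GLSZM_FEATURES)), GLSZM_FEATURES))
  }
  zones <- list()
  for (g in seq_len(ng)) {
    m <- !is.na(lev) & lev == g
    if (!any(m)) next
    labs <- label_components_26(m)
    sz <- tabulate(labs[labs > 0])
    if (length(sz)) zones[[length(zones) + 1L]] <- cbind(level = g, size = sz)
  }
  zs <- do.call(rbind, zones)
  maxsz <- max(zs[, "size"])
  S <- matrix(0, ng, maxsz)
  for (r in seq_len(nrow(zs)))
    S[zs[r, "level"], zs[r, "size"]] <- S[zs[r, "level"], zs[r, "size"]] + 1
  nz <- sum(S)
  p <- S / nz
  i <- row(S); z <- col(S)
  si <- rowSums(S); sz_ <- colSums(S)
  mu_i <- sum(p * i); mu_z <- sum(p * z)
  c(SmallAreaEmphasis = sum(p / z^2),
    LargeAreaEmphasis = sum(p * z^2),
    GrayLevelNonUniformity = sum(si^2) / nz,
    GrayLevelNonUniformityNormalized = sum(si^2) / nz^2,
    SizeZoneNonUniformity = sum(sz_^2) / nz,
    SizeZoneNonUniformityNormalized = sum(sz_^2) / nz^2,
    ZonePercentage = nz / nv,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    ZoneVariance = sum(p * (z - mu_z)^2),
    ZoneEntropy = -sum(p * log2(p + TEXTURE_EPS)),
    LowGrayLevelZoneEmphasis = sum(p / i^2),
    HighGrayLevelZoneEmphasis = sum(p * i^2),
    SmallAreaLowGrayLevelEmphasis = sum(p / (i^2 * z^2)),
    SmallAreaHighGrayLevelEmphasis = sum(p * i^2 / z^2),
    LargeAreaLowGrayLevelEmphasis = sum(p * z^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = sum(p * i^2 * z^2))
}

GLDM_FEATURES <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
                   "GrayLevelNonUniformity", "DependenceNonUniformity",
                   "DependenceNonUniformityNormalized", "GrayLevelVariance",
                   "DependenceVariance", "DependenceEntropy",
                   "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
                   "SmallDependenceLowGrayLevelEmphasis",
                   "SmallDependenceHighGrayLevelEmphasis",
                   "LargeDependenceLowGrayLevelEmphasis",
                   "LargeDependenceHighGrayLevelEmphasis")

#' Gray-level dependence matrix features
#'
#' For every in-mask voxel of level `i`, the dependence count is the number
#' of 26-neighbours whose level differs from `i` by at most `alpha`
#' (default 0); the stored dependence size is that count plus one (the
#' centre voxel), so size-weighted features are well defined.
#' `GrayLevelVariance` is `sum_ik p(i,k) (i - mu)^2` with the probabilities
#' normalized over all in-mask voxels.
#'
#' @inheritParams glcm_features
#' @param alpha dependence tolerance on the level difference (default 0).
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(region, alpha = 0) {
  lev <- region$levels
  ng <- region$n_levels
  nv <- sum(!is.na(lev))
  if (nv < 1) {
    warning("empty region: GLDM features set to 0")
    return(stats::setNames(numeric(length(GLDM_FEATURES)), GLDM_FEATURES))
  }
  offs <- all_offsets_3d()
  d <- dim(lev)
  dep <- array(0L, dim = d)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    rg <- shift_ranges(d, off)
    if (is.null(rg)) next
    xr <- rg[[1]]; yr <- rg[[2]]; zr <- rg[[3]]
    a <- lev[xr, yr, zr, drop = FALSE]
    b <- lev[xr + off[1], yr + off[2], zr + off[3], drop = FALSE]
    inc <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    dd <- dep[xr, yr, zr, drop = FALSE]
    dd[inc] <- dd[inc] + 1L
    dep[xr, yr, zr] <- dd
  }
  ok <- !is.na(lev)
  jj <- dep[ok] + 1L  # dependence size incl. the centre voxel
  ii <- lev[ok]
  maxj <- max(jj)
  D <- matrix(0, ng, maxj)
  tab <- tabulate((ii - 1L) * maxj + jj, nbins = ng * maxj)
  D <- matrix(tab, ng, maxj, byrow = TRUE)
  nz <- sum(D)
  p <- D / nz
  i <- row(D); j <- col(D)
  di <- rowSums(D); dj <- colSums(D)
  mu_i <- sum(p * i); mu_j <- sum(p * j)
  c(SmallDependenceEmphasis = sum(p / j^2),
    LargeDependenceEmphasis = sum(p * j^2),
    GrayLevelNonUniformity = sum(di^2) / nz,
    DependenceNonUniformity = sum(dj^2) / nz,
    DependenceNonUniformityNormalized = sum(dj^2) / nz^2,
    GrayLevelVariance = sum(p * (i - mu_i)^2),
    DependenceVariance = sum(p * (j - mu_j)^2),
    DependenceEntropy = -sum(p * log2(p + TEXTURE_EPS)),
    LowGrayLevelEmphasis = sum(p / i^2),
    HighGrayLevelEmphasis = sum(p * i^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (i^2 * j^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * i^2 / j^2),
    LargeDependenceLowGrayLevelEmphasis = sum(p * j^2 / i^2),
    LargeDependenceHighGrayLevelEmphasis = sum(p * i^2 * j^2))
}

NGTDM_FEATURES <- c("Coarseness", "Contrast", "Busyness", "Complexity",
                    "Strength")

#' Neighbourhood gray-tone difference matrix features
#'
#' For every in-mask voxel with at least one in-mask 26-neighbour, the
#' absolute difference between its level and the mean level of those
#' neighbours is accumulated per level.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(region) {
  lev <- region$levels
  ng <- region$n_levels
  nv_all <- sum(!is.na(lev))
  if (nv_all < 1) {
    warning("empty region: NGTDM features set to 0")
    return(stats::setNames(numeric(length(NGTDM_FEATURES)), NGTDM_FEATURES))
  }
  offs <- all_offsets_3d()
  d <- dim(lev)
  nb_sum <- array(0, dim = d)
  nb_cnt <- array(0L, dim = d)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    rg <- shift_ranges(d, off)
    if (is.null(rg)) next
    xr <- rg[[1]]; yr <- rg[[2]]; zr <- rg[[3]]
    b <- lev[xr + off[1], yr + off[2], zr + off[3], drop = FALSE]
    add <- ifelse(is.na(b), 0, b)
    cnt <- !is.na(b)
    ss <- nb_sum[xr, yr, zr, drop = FALSE]; ss <- ss + add
    nb_sum[xr, yr, zr] <- ss
    cc <- nb_cnt[xr, yr, zr, drop = FALSE]; cc <- cc + cnt
    nb_cnt[xr, yr, zr] <- cc
  }
  ok <- !is.na(lev) & nb_cnt > 0
  nvp <- sum(ok)
  ii <- lev[ok]
  avg <- nb_sum[ok] / nb_cnt[ok]
  s <- numeric(ng); n_i <- numeric(ng)
  for (g in seq_len(ng)) {
    sel <- ii == g
    n_i[g] <- sum(sel)
    s[g] <- sum(abs(g - avg[sel]))
  }
  p <- n_i / nvp
  act <- which(p > 0)
  ngp <- length(act)
  coarse_den <- sum(p * s)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(act, act, "-")^2) /
      (ngp * (ngp - 1)) * sum(s) / nvp
  } else 0
  # denominator is the full double sum over ordered pairs with p > 0
  busy_den <- sum(abs(outer(act * p[act], act * p[act], "-")))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  complexity <- if (nvp > 0 && ngp > 1) {
    tot <- 0
    for (a in act) for (b in act)
      if (a != b)
        tot <- tot + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    tot / nvp
  } else 0
  strength <- if (sum(s) > 0 && ngp > 1) {
    tot <- 0
    for (a in act) for (b in act)
      if (a != b) tot <- tot + (p[a] + p[b]) * (a - b)^2
    tot / sum(s)
  } else 0
  c(Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength)
}
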