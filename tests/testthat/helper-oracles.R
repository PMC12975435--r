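# Brute-force oracles: deliberately naive loop implementations, independent
# of the package's vectorized paths.

oracle_eps <- .Machine$double.eps

oracle_directions <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  g[apply(g, 1, function(v) { nz <- v[v != 0]; nz[1] > 0 }), , drop = FALSE]
}

oracle_all_offsets <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

# ---- GLCM ------------------------------------------------------------
oracle_glcm_matrix <- function(lev, off) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  M <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    q <- c(x, y, z) + off
    if (!in_grid(q, d)) next
    b <- lev[q[1], q[2], q[3]]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

oracle_glcm_features_one <- function(P) {
  ng <- nrow(P)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) { px[i] <- px[i] + P[i, j]; py[j] <- py[j] + P[i, j] }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  pxmy <- numeric(ng); pxpy <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pxmy[abs(i - j) + 1] <- pxmy[abs(i - j) + 1] + P[i, j]
    pxpy[i + j - 1] <- pxpy[i + j - 1] + P[i, j]
  }
  f <- c()
  acc <- ja <- cp <- cs <- ct <- con <- cor_num <- 0
  idm <- idmn <- idn <- idf <- invvar <- ss <- 0
  hxy <- hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + i * j * p
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    con <- con + (i - j)^2 * p
    cor_num <- cor_num + i * j * p
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    idf <- idf + p / (1 + abs(i - j))
    idn <- idn + p / (1 + abs(i - j) / ng)
    if (i != j) invvar <- invvar + p / (i - j)^2
    ss <- ss + (i - mux)^2 * p
    hxy <- hxy - p * log2(p + oracle_eps)
    hxy1 <- hxy1 - p * log2(px[i] * py[j] + oracle_eps)
    hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j] + oracle_eps)
  }
  hx <- -sum(px * log2(px + oracle_eps)); hy <- -sum(py * log2(py + oracle_eps))
  da <- sum((0:(ng - 1)) * pxmy)
  keep <- which(px > 0)
  mcc <- if (length(keep) <= 1) 1 else {
    Q <- matrix(0, length(keep), length(keep))
    for (ii in seq_along(keep)) for (jj in seq_along(keep)) {
      s <- 0
      for (kk in seq_along(keep))
        if (py[keep[kk]] > 0)
          s <- s + P[keep[ii], keep[kk]] * P[keep[jj], keep[kk]] /
            (px[keep[ii]] * py[keep[kk]])
      Q[ii, jj] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (ev[2] < 1e-12) 0 else sqrt(ev[2])  # degenerate-value guard, as in the package
  }
  c(Autocorrelation = acc, JointAverage = mux, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = con,
    Correlation = if (sx * sy > 0) (cor_num - mux * muy) / (sx * sy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmy * log2(pxmy + oracle_eps)),
    DifferenceVariance = sum(((0:(ng - 1)) - da)^2 * pxmy),
    JointEnergy = sum(P^2), JointEntropy = hxy,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = {  # degenerate-value guard, as in the package
      u2 <- max(0, 1 - exp(-2 * (hxy2 - hxy)))
      if (u2 < 1e-12) 0 else sqrt(u2)
    },
    Idm = idm, Idmn = idmn, Id = idf, Idn = idn,
    InverseVariance = invvar, MaximumProbability = max(P),
    SumAverage = sum((2:(2 * ng)) * pxpy),
    SumEntropy = -sum(pxpy * log2(pxpy + oracle_eps)),
    SumSquares = ss, MCC = mcc)
}

oracle_glcm_features <- function(lev) {
  dirs <- oracle_directions()
  acc <- NULL; nd <- 0
  for (r in seq_len(nrow(dirs))) {
    M <- oracle_glcm_matrix(lev, dirs[r, ])
    if (sum(M) == 0) next
    f <- oracle_glcm_features_one(M / sum(M))
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

# ---- GLRLM -----------------------------------------------------------
oracle_glrlm_matrix <- function(lev, off) {
  d <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  R <- matrix(0, ng, max(d))
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    p <- c(x, y, z)
    prev <- p - off
    if (in_grid(prev, d)) next  # not a line start
    # walk the whole grid line, run-length encoding as we go
    cur_lev <- NA_integer_; cur_len <- 0L
    while (in_grid(p, d)) {
      v <- lev[p[1], p[2], p[3]]
      if (!is.na(v) && !is.na(cur_lev) && v == cur_lev) {
        cur_len <- cur_len + 1L
      } else {
        if (!is.na(cur_lev)) R[cur_lev, cur_len] <- R[cur_lev, cur_len] + 1
        cur_lev <- v
        cur_len <- 1L
      }
      p <- p + off
    }
    if (!is.na(cur_lev)) R[cur_lev, cur_len] <- R[cur_lev, cur_len] + 1
  }
  R
}

oracle_rl_features <- function(R, n_voxels, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  nr <- sum(R)
  ng <- nrow(R); nl <- ncol(R)
  p <- R / nr
  mu_i <- mu_l <- 0
  for (i in 1:ng) for (l in 1:nl) { mu_i <- mu_i + p[i, l] * i; mu_l <- mu_l + p[i, l] * l }
  sre <- lre <- glv <- rv <- re <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- 0
  for (i in 1:ng) for (l in 1:nl) {
    q <- p[i, l]
    sre <- sre + q / l^2; lre <- lre + q * l^2
    glv <- glv + q * (i - mu_i)^2; rv <- rv + q * (l - mu_l)^2
    re <- re - q * log2(q + oracle_eps)
    lgl <- lgl + q / i^2; hgl <- hgl + q * i^2
    srl <- srl + q / (i^2 * l^2); srh <- srh + q * i^2 / l^2
    lrl <- lrl + q * l^2 / i^2; lrh <- lrh + q * i^2 * l^2
  }
  ri <- rowSums(R); rl_ <- colSums(R)
  base <- c(sre, lre, sum(ri^2) / nr, sum(ri^2) / nr^2, sum(rl_^2) / nr,
            sum(rl_^2) / nr^2, nr / n_voxels, glv, rv, re, lgl, hgl,
            srl, srh, lrl, lrh)
  names(base) <- if (kind == "run") {
    c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
      "RunLengthNonUniformityNormalized", "RunPercentage",
      "GrayLevelVariance", "RunVariance", "RunEntropy",
      "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
      "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
      "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  } else {
    c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
      "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
      "SizeZoneNonUniformityNormalized", "ZonePercentage",
      "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
      "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
      "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
      "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  }
  base
}

oracle_glrlm_features <- function(lev) {
  dirs <- oracle_directions()
  nv <- sum(!is.na(lev))
  acc <- NULL
  for (r in seq_len(nrow(dirs))) {
    R <- oracle_glrlm_matrix(lev, dirs[r, ])
    f <- oracle_rl_features(R, nv, "run")
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(dirs)
}

# ---- GLSZM -----------------------------------------------------------
oracle_zones <- function(lev) {
  d <- dim(lev)
  offs <- oracle_all_offsets()
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(lev[x, y, z])) next
    g <- lev[x, y, z]
    stack <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (in_grid(q, d) && !seen[q[1], q[2], q[3]] &&
            !is.na(lev[q[1], q[2], q[3]]) && lev[q[1], q[2], q[3]] == g) {
          seen[q[1], q[2], q[3]] <- TRUE
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(level = g, size = size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(lev) {
  zs <- oracle_zones(lev)
  ng <- max(lev, na.rm = TRUE)
  S <- matrix(0, ng, max(zs[, "size"]))
  for (r in seq_len(nrow(zs)))
    S[zs[r, "level"], zs[r, "size"]] <- S[zs[r, "level"], zs[r, "size"]] + 1
  oracle_rl_features(S, sum(!is.na(lev)), "zone")
}

# ---- GLDM ------------------------------------------------------------
oracle_gldm_features <- function(lev, alpha = 0) {
  d <- dim(lev)
  offs <- oracle_all_offsets()
  recs <- list()
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    k <- 0L
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]) &&
          abs(lev[q[1], q[2], q[3]] - a) <= alpha) k <- k + 1L
    }
    recs[[length(recs) + 1L]] <- c(i = a, j = k + 1L)
  }
  m <- do.call(rbind, recs)
  ng <- max(lev, na.rm = TRUE)
  D <- matrix(0, ng, max(m[, "j"]))
  for (r in seq_len(nrow(m))) D[m[r, "i"], m[r, "j"]] <- D[m[r, "i"], m[r, "j"]] + 1
  nz <- sum(D); p <- D / nz
  mu_i <- mu_j <- 0
  for (i in 1:nrow(D)) for (j in 1:ncol(D)) { mu_i <- mu_i + p[i, j] * i; mu_j <- mu_j + p[i, j] * j }
  sde <- lde <- glv <- dv <- de <- lgl <- hgl <- sdl <- sdh <- ldl <- ldh <- 0
  for (i in 1:nrow(D)) for (j in 1:ncol(D)) {
    q <- p[i, j]
    sde <- sde + q / j^2; lde <- lde + q * j^2
    glv <- glv + q * (i - mu_i)^2; dv <- dv + q * (j - mu_j)^2
    de <- de - q * log2(q + oracle_eps)
    lgl <- lgl + q / i^2; hgl <- hgl + q * i^2
    sdl <- sdl + q / (i^2 * j^2); sdh <- sdh + q * i^2 / j^2
    ldl <- ldl + q * j^2 / i^2; ldh <- ldh + q * i^2 * j^2
  }
  c(SmallDependenceEmphasis = sde, LargeDependenceEmphasis = lde,
    GrayLevelNonUniformity = sum(rowSums(D)^2) / nz,
    DependenceNonUniformity = sum(colSums(D)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(D)^2) / nz^2,
    GrayLevelVariance = glv, DependenceVariance = dv, DependenceEntropy = de,
    LowGrayLevelEmphasis = lgl, HighGrayLevelEmphasis = hgl,
    SmallDependenceLowGrayLevelEmphasis = sdl,
    SmallDependenceHighGrayLevelEmphasis = sdh,
    LargeDependenceLowGrayLevelEmphasis = ldl,
    LargeDependenceHighGrayLevelEmphasis = ldh)
}

# ---- NGTDM -----------------------------------------------------------
oracle_ngtdm_features <- function(lev) {
  d <- dim(lev)
  offs <- oracle_all_offsets()
  ng <- max(lev, na.rm = TRUE)
  s <- numeric(ng); n_i <- numeric(ng); nvp <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lev[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      q <- c(x, y, z) + offs[r, ]
      if (in_grid(q, d) && !is.na(lev[q[1], q[2], q[3]]))
        nb <- c(nb, lev[q[1], q[2], q[3]])
    }
    if (length(nb) == 0) next
    nvp <- nvp + 1
    n_i[a] <- n_i[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  p <- n_i / nvp
  act <- which(p > 0); ngp <- length(act)
  coarse <- if (sum(p * s) > 0) 1 / sum(p * s) else 1e6
  contrast <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) contrast <- contrast + p[i] * p[j] * (i - j)^2
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / nvp
  }
  den <- 0
  for (i in act) for (j in act) den <- den + abs(i * p[i] - j * p[j])
  busy <- if (den > 0) sum(p * s) / den else 0
  compl <- 0
  if (ngp > 1) {
    for (i in act) for (j in act)
      if (i != j) compl <- compl + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
    compl <- compl / nvp
  }
  stren <- 0
  if (ngp > 1 && sum(s) > 0) {
    for (i in act) for (j in act) if (i != j) stren <- stren + (p[i] + p[j]) * (i - j)^2
    stren <- stren / sum(s)
  }
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = compl, Strength = stren)
}

# ---- survival oracles ------------------------------------------------
# explicit Cox partial log-likelihood (no ties) for a single covariate
oracle_cox_loglik <- function(beta, x, times, events) {
  ll <- 0
  for (i in which(events == 1)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

oracle_cox_coef <- function(x, times, events) {
  stats::optimize(function(b) -oracle_cox_loglik(b, x, times, events),
                  interval = c(-10, 10), tol = 1e-9)$minimum
}

# hand product-limit table: returns survival at each distinct event time
oracle_km <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    t0 <- ev_times[k]
    n_risk <- sum(times >= t0)
    d <- sum(times == t0 & events == 1)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  data.frame(time = ev_times, survival = out)
}

# ---- fixtures --------------------------------------------------------
random_region <- function(seed, dims = c(4, 4, 4), ng = 4, p_mask = 0.85) {
  set.seed(seed)
  lev <- array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
  mask <- array(runif(prod(dims)) < p_mask, dim = dims)
  while (sum(mask) < 2) mask[sample(prod(dims), 1)] <- TRUE
  lev[!mask] <- NA_integer_
  # re-map so levels are 1..max observed (discretize contract)
  obs <- sort(unique(lev[!is.na(lev)]))
  lev[!is.na(lev)] <- match(lev[!is.na(lev)], obs)
  list(levels = lev, n_levels = max(lev, na.rm = TRUE))
}
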