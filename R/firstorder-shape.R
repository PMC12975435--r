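FIRSTORDER_FEATURES <- c("Energy", "TotalEnergy", "Entropy", "Minimum",
                         "Percentile10", "Percentile90", "Maximum", "Mean",
                         "Median", "InterquartileRange", "Range",
                         "MeanAbsoluteDeviation",
                         "RobustMeanAbsoluteDeviation", "RootMeanSquared",
                         "Skewness", "Kurtosis", "Variance", "Uniformity")

FIRSTORDER_EXTRA_FEATURES <- c("StandardDeviation", "CoefficientOfVariation",
                               "MedianAbsoluteDeviation",
                               "QuartileCoefficientOfDispersion",
                               "TotalLesionGlycolysis")

#' First-order intensity features
#'
#' The 18 standard first-order statistics of the in-mask intensities.
#' `Entropy` and `Uniformity` are computed on the fixed-bin-width histogram
#' (same 0.1 default width as the texture discretization). Skewness and
#' kurtosis use population moments; kurtosis is not excess-corrected. On a
#' zero-variance region the moment ratios fall back to 0.
#'
#' @param values in-mask intensities.
#' @param voxel_volume volume of one voxel in mm^3 (for `TotalEnergy`).
#' @param width histogram bin width.
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(values, voxel_volume = 1, width = 0.1) {
  stop_if_not(length(values) > 0, "empty region")
  n <- length(values)
  m <- mean(values)
  v <- pop_var(values)
  hist_p <- {
    lv <- discretize(values, width)$levels
    tabulate(lv) / n
  }
  hist_p <- hist_p[hist_p > 0]
  q <- stats::quantile(values, c(0.10, 0.25, 0.75, 0.90), names = FALSE)
  rob <- values[values >= q[1] & values <= q[4]]
  m3 <- mean((values - m)^3)
  m4 <- mean((values - m)^4)
  c(Energy = sum(values^2),
    TotalEnergy = voxel_volume * sum(values^2),
    Entropy = -sum(hist_p * log2(hist_p + TEXTURE_EPS)),
    Minimum = min(values),
    Percentile10 = q[1],
    Percentile90 = q[4],
    Maximum = max(values),
    Mean = m,
    Median = stats::median(values),
    InterquartileRange = q[3] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - m)),
    RobustMeanAbsoluteDeviation = mean(abs(rob - mean(rob))),
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (v > 0) m3 / v^1.5 else 0,
    Kurtosis = if (v > 0) m4 / v^2 else 0,
    Variance = v,
    Uniformity = sum(hist_p^2))
}

#' @rdname firstorder_features
#' @param region_volume total region volume in mm^3 (for
#'   `TotalLesionGlycolysis`, reported in SUV x ml).
#' @export
firstorder_extra_features <- function(values, region_volume = length(values)) {
  m <- mean(values)
  s <- pop_sd(values)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  c(StandardDeviation = s,
    CoefficientOfVariation = if (abs(m) > 0) s / m else 0,
    MedianAbsoluteDeviation = stats::median(abs(values - stats::median(values))),
    QuartileCoefficientOfDispersion =
      if ((q[2] + q[1]) != 0) (q[2] - q[1]) / (q[2] + q[1]) else 0,
    TotalLesionGlycolysis = m * region_volume / 1000)
}

SHAPE_FEATURES <- c("VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
                    "Sphericity", "Compactness1", "Compactness2",
                    "SphericalDisproportion", "Maximum3DDiameter",
                    "Maximum2DDiameterSlice", "MajorAxisLength",
                    "MinorAxisLength", "LeastAxisLength", "Elongation",
                    "Flatness")

# physical centre coordinates (mm) of in-mask voxels, rows = voxels
mask_coords_mm <- function(mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx - 1, 2, spacing, "*")
}

# voxel-face surface area: every face between an in-mask voxel and an
# out-of-mask (or out-of-grid) neighbour contributes the face area
voxel_surface_area <- function(mask, spacing) {
  d <- dim(mask)
  area <- 0
  face <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
            spacing[1] * spacing[2])
  for (ax in 1:3) {
    pad_d <- d
    pad_d[ax] <- d[ax] + 2L
    padded <- array(FALSE, dim = pad_d)
    idx <- lapply(1:3, function(a) if (a == ax) 1 + seq_len(d[a]) else seq_len(d[a]))
    padded[idx[[1]], idx[[2]], idx[[3]]] <- mask
    sl <- function(shift) {
      i <- idx
      i[[ax]] <- i[[ax]] + shift
      padded[i[[1]], i[[2]], i[[3]]]
    }
    area <- area + face[ax] * (sum(mask & !sl(-1)) + sum(mask & !sl(1)))
  }
  area
}

max_pairwise_dist <- function(coords) {
  if (nrow(coords) < 2) return(0)
  max(stats::dist(coords))
}

# surface voxels: in-mask voxels with at least one out-of-mask 6-neighbour
surface_voxels <- function(mask) {
  d <- dim(mask)
  surf <- array(FALSE, dim = d)
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- array(FALSE, dim = d)
    src <- lapply(1:3, function(a) seq_len(d[a]))
    dst <- src
    rng <- seq_len(d[ax] - 1L)
    if (s == 1L) { src[[ax]] <- rng + 1L; dst[[ax]] <- rng }
    else { src[[ax]] <- rng; dst[[ax]] <- rng + 1L }
    nb[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
    surf <- surf | (mask & !nb)
  }
  # grid-boundary voxels are surface by definition
  for (ax in 1:3) {
    idx <- lapply(1:3, function(a) seq_len(d[a]))
    idx[[ax]] <- c(1L, d[ax])
    bnd <- array(FALSE, dim = d)
    bnd[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
    surf <- surf | (mask & bnd)
  }
  surf
}

#' Shape features of a binary mask
#'
#' Fourteen 3D shape descriptors computed on the voxel mask: voxel volume,
#' voxel-face surface area (and derived sphericity/compactness indices),
#' maximum 3D and in-slice diameters (between surface-voxel centres), and
#' principal-axis lengths from the eigenvalues of the physical-coordinate
#' covariance (axis length = 4 sqrt(lambda)).
#'
#' @param mask logical 3D array.
#' @param spacing voxel spacing (mm).
#' @return named numeric vector of 14 features.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  stop_if_not(any(mask), "empty mask")
  n <- sum(mask)
  vol <- n * prod(spacing)
  area <- voxel_surface_area(mask, spacing)
  surf <- surface_voxels(mask)
  sc <- mask_coords_mm(surf, spacing)
  d3 <- max_pairwise_dist(sc)
  # max in-plane diameter over slices of the third axis
  d2 <- 0
  for (z in unique(which(surf, arr.ind = TRUE)[, 3])) {
    m2 <- surf[, , z, drop = FALSE]
    cc <- mask_coords_mm(m2, spacing)
    d2 <- max(d2, max_pairwise_dist(cc[, 1:2, drop = FALSE]))
  }
  co <- mask_coords_mm(mask, spacing)
  if (n > 1) {
    cv <- stats::cov(co) * (n - 1) / n
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  sphericity <- (36 * pi * vol^2)^(1 / 3) / area
  c(VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = sphericity,
    Compactness1 = vol / (sqrt(pi) * area^1.5),
    Compactness2 = 36 * pi * vol^2 / area^3,
    SphericalDisproportion = 1 / sphericity,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}
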