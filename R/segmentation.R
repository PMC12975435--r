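#' Resample an SUV volume to isotropic spacing
#'
#' Trilinear interpolation of intensities onto a grid with the target voxel
#' spacing on all axes. The output grid keeps the input origin; output voxel
#' centres span the physical extent of the input voxel centres. Masks should
#' be resampled with [resample_mask()] (nearest neighbour) instead.
#'
#' @param volume a [suv_volume()].
#' @param target target spacing in mm (scalar, > 0).
#' @return A resampled `suv_volume`. If the input is already at the target
#'   spacing it is returned unchanged.
#' @export
resample_isotropic <- function(volume, target = 1) {
  stopifnot(inherits(volume, "suv_volume"))
  stop_if_not(target > 0, "target spacing must be > 0")
  stop_if_not(length(volume$data) > 0, "empty volume")
  if (all(abs(volume$spacing - target) < 1e-12)) return(volume)
  out <- trilinear_resample(volume$data, volume$spacing, target)
  suv_volume(pmax(out, 0), spacing = rep(target, 3), origin = volume$origin)
}

#' @rdname resample_isotropic
#' @param mask logical 3D array aligned with `volume`'s grid.
#' @param spacing spacing of the mask grid (mm).
#' @export
resample_mask <- function(mask, spacing, target = 1) {
  if (all(abs(spacing - target) < 1e-12)) return(mask)
  d <- dim(mask)
  new_d <- pmax(2L, floor((d - 1) * spacing / target) + 1L)
  idx <- lapply(1:3, function(a) {
    pos <- (seq_len(new_d[a]) - 1) * target / spacing[a] + 1
    pmin(pmax(round(pos), 1L), d[a])
  })
  mask[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

trilinear_resample <- function(arr, spacing, target) {
  d <- dim(arr)
  new_d <- pmax(2L, floor((d - 1) * spacing / target) + 1L)
  # fractional input index of each output voxel centre, per axis
  pos <- lapply(1:3, function(a) {
    p <- (seq_len(new_d[a]) - 1) * target / spacing[a] + 1
    pmin(pmax(p, 1), d[a])
  })
  lo <- lapply(seq_along(pos), function(a) pmin(floor(pos[[a]]), d[a] - 1L))
  fr <- lapply(seq_along(pos), function(a) pos[[a]] - lo[[a]])
  out <- array(0, dim = new_d)
  ix <- lo[[1]]; fx <- fr[[1]]
  iy <- lo[[2]]; fy <- fr[[2]]
  iz <- lo[[3]]; fz <- fr[[3]]
  wx0 <- 1 - fx; wy0 <- 1 - fy; wz0 <- 1 - fz
  for (dz in 0:1) {
    wz <- if (dz == 0) wz0 else fz
    for (dy in 0:1) {
      wy <- if (dy == 0) wy0 else fy
      sub <- arr[, iy + dy, iz + dz, drop = FALSE]
      # interpolate along x for this (dy, dz) corner pair
      v0 <- sub[ix, , , drop = FALSE] * wx0
      v1 <- sub[ix + 1L, , , drop = FALSE] * fx
      w <- outer(rep(1, new_d[1]), outer(wy, wz))
      dim(w) <- new_d
      out <- out + (v0 + v1) * w
    }
  }
  out
}

#' Liver reference statistics for PERCIST thresholding
#'
#' Mean and population SD of SUV over voxels whose centres lie within the
#' liver reference sphere (3 cm diameter by default), emulating the hepatic
#' volume of interest placed in the right lobe.
#'
#' @param volume a [suv_volume()].
#' @param center sphere centre in mm.
#' @param diameter sphere diameter in mm (default 30).
#' @return list of class `liver_reference`: `center`, `diameter`, `mean`,
#'   `sd` (population), `n_voxels`.
#' @export
liver_reference <- function(volume, center, diameter = 30) {
  stopifnot(inherits(volume, "suv_volume"))
  r <- diameter / 2
  ext <- (dim(volume$data) - 1) * volume$spacing + volume$origin
  if (any(center - r < volume$origin) || any(center + r > ext))
    stop("liver reference sphere extends outside the volume", call. = FALSE)
  m <- sphere_mask(dim(volume$data), volume$spacing, center - volume$origin, r)
  vals <- volume$data[m]
  stop_if_not(length(vals) > 0, "liver sphere contains no voxel centres")
  structure(list(center = center, diameter = diameter,
                 mean = mean(vals), sd = pop_sd(vals),
                 n_voxels = length(vals)),
            class = "liver_reference")
}

#' PERCIST-based segmentation threshold
#'
#' `T = 1.5 * mean liver SUV + 2 * SD`, the liver-referenced lesion
#' threshold used for tumour delineation.
#'
#' @param ref a [liver_reference()].
#' @return threshold in SUV units.
#' @export
percist_threshold <- function(ref) {
  stopifnot(inherits(ref, "liver_reference"))
  1.5 * ref$mean + 2 * ref$sd
}

#' Label 26-connected components of a 3D logical mask
#'
#' Iterative minimum-label propagation over the 26-neighbourhood.
#'
#' @param mask logical 3D array.
#' @return integer array; 0 = background, components numbered 1..k in
#'   first-voxel order.
#' @export
label_components_26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0, dim = d)
  lab[mask] <- which(mask)
  if (!any(mask)) return(lab)
  pad <- function(a) {
    out <- array(Inf, dim = d + 2L)
    out[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- a
    out
  }
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  labw <- lab
  labw[!mask] <- Inf
  repeat {
    p <- pad(labw)
    best <- labw
    for (k in seq_len(nrow(offs))) {
      sh <- p[(2:(d[1] + 1)) + offs$dx[k],
              (2:(d[2] + 1)) + offs$dy[k],
              (2:(d[3] + 1)) + offs$dz[k]]
      best <- pmin(best, sh)
    }
    best[!mask] <- Inf
    if (all(best[mask] == labw[mask])) break
    labw <- best
  }
  lab <- array(0L, dim = d)
  ids <- sort(unique(labw[mask]))
  lab[mask] <- match(labw[mask], ids)
  lab
}

#' Segment tumour lesions by liver-referenced thresholding
#'
#' Keeps voxels with `SUV >= T` (inclusive), removes user-supplied exclusion
#' masks (the file-based stand-in for manual corrections of brain, kidney,
#' bladder uptake), groups the remainder into 26-connected components and
#' drops components below the minimum size.
#'
#' @param volume a [suv_volume()] (expected at isotropic 1 mm spacing).
#' @param threshold SUV threshold `T` (e.g. from [percist_threshold()]).
#' @param exclusions list of logical arrays aligned with the volume grid.
#' @param min_size minimum component size in voxels (default 64).
#' @return list of class `segmentation_result`: logical `mask`, `threshold`,
#'   integer `labels` array, `component_sizes` (voxels per kept component),
#'   `n_excluded_voxels`.
#' @export
segment_lesions <- function(volume, threshold, exclusions = list(),
                            min_size = 64) {
  stopifnot(inherits(volume, "suv_volume"))
  fg <- volume$data >= threshold
  n_exc <- 0L
  for (ex in exclusions) {
    stop_if_not(identical(dim(ex), dim(volume$data)),
                "exclusion mask shape must match the volume")
    n_exc <- n_exc + sum(fg & ex)
    fg <- fg & !ex
  }
  if (!any(fg)) {
    warning("no voxel at or above the threshold; empty segmentation")
    return(structure(list(mask = fg, threshold = threshold,
                          labels = array(0L, dim = dim(volume$data)),
                          component_sizes = integer(0),
                          n_excluded_voxels = n_exc),
                     class = "segmentation_result"))
  }
  labs <- label_components_26(fg)
  sizes <- tabulate(labs[labs > 0])
  keep <- which(sizes >= min_size)
  labs[!(labs %in% keep)] <- 0L
  # renumber kept components consecutively
  if (length(keep)) {
    labs[labs > 0] <- match(labs[labs > 0], keep)
    sizes <- sizes[keep]
  } else sizes <- integer(0)
  structure(list(mask = labs > 0, threshold = threshold, labels = labs,
                 component_sizes = sizes, n_excluded_voxels = n_exc),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation at T = %.3f SUV: %d component(s), %d voxel(s)\n",
              x$threshold, length(x$component_sizes), sum(x$mask)))
  invisible(x)
}
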