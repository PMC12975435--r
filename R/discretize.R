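#' Fixed-bin-width gray-level discretization
#'
#' Maps intensities to integer gray levels with a fixed bin width, anchored
#' at the region minimum:
#' `level(x) = floor(x / width) - floor(min(x) / width) + 1`.
#' The default 0.1 SUV width is the PET discretization used throughout the
#' feature extraction; each image type (original volume and every wavelet
#' sub-band) is discretized independently.
#'
#' @param values numeric intensities of the in-mask voxels (non-empty).
#' @param width bin width (> 0), default 0.1.
#' @return list of class `discretized_region`: integer `levels` (same length
#'   as `values`), `n_levels` (Ng = max level), `width`, `origin_bin`
#'   (`floor(min/width)`, enough to reproduce the mapping).
#' @export
discretize <- function(values, width = 0.1) {
  stop_if_not(length(values) > 0, "cannot discretize an empty region")
  stop_if_not(is.numeric(width) && width > 0, "bin width must be > 0")
  stop_if_not(all(is.finite(values)), "intensities must be finite")
  origin_bin <- floor(min(values) / width)
  lev <- as.integer(floor(values / width) - origin_bin + 1)
  structure(list(levels = lev, n_levels = max(lev), width = width,
                 origin_bin = origin_bin),
            class = "discretized_region")
}

# Discretize the in-mask voxels of a 3D image into a cropped integer-level
# array (NA outside the mask), the working representation for all texture
# matrices. Cropping to the mask bounding box keeps the texture scans small.
discretize_region <- function(image, mask, width = 0.1) {
  stop_if_not(identical(dim(image), dim(mask)), "image/mask shape mismatch")
  stop_if_not(any(mask), "empty mask")
  idx <- which(mask, arr.ind = TRUE)
  rng <- apply(idx, 2, range)
  sub <- image[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
               rng[1, 3]:rng[2, 3], drop = FALSE]
  subm <- mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
               rng[1, 3]:rng[2, 3], drop = FALSE]
  dz <- discretize(sub[subm], width)
  lev <- array(NA_integer_, dim = dim(sub))
  lev[subm] <- dz$levels
  list(levels = lev, n_levels = dz$n_levels, width = width,
       origin_bin = dz$origin_bin, values = sub[subm])
}
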