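#' Specify a synthetic PET phantom
#'
#' Describes a 3D SUV phantom: a uniform background, a liver reference sphere
#' (30 mm diameter by default, matching the PERCIST liver VOI), one or more
#' hot lesions, optional organ "exclusion" spheres emulating physiologic
#' uptake that a reader would strip out, and additive Gaussian noise.
#'
#' Lesions are spheres given in physical mm. Texture kind `"smooth"` sets all
#' lesion voxels to the amplitude; `"speckled"` multiplies each lesion voxel
#' by an independent lognormal factor so texture-variance features are
#' non-degenerate.
#'
#' @param shape integer length-3 grid shape (voxels).
#' @param spacing voxel spacing in mm (length 3).
#' @param background background SUV level.
#' @param liver list with `center` (mm), `mean`, `sd`, optional `diameter`
#'   (mm, default 30), or `NULL` for no liver sphere.
#' @param lesions list of lesions; each a list with `center` (mm), `radius`
#'   (mm), `amplitude` (SUV) and `texture` ("smooth" or "speckled").
#' @param exclusions list of spheres (`center`, `radius`) to emit as
#'   exclusion masks.
#' @param noise_sd SD of additive Gaussian noise.
#' @param speckle_sd SD (log scale) of the speckled lognormal multiplier.
#' @param seed integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                         background = 1.0,
                         liver = list(center = c(18, 18, 18), mean = 2.0, sd = 0.2),
                         lesions = list(list(center = c(46, 46, 46), radius = 7,
                                             amplitude = 8, texture = "speckled")),
                         exclusions = list(),
                         noise_sd = 0.05, speckle_sd = 0.15, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stop_if_not(length(shape) == 3L && all(shape >= 4L), "`shape` must be 3 sizes >= 4")
  stop_if_not(all(spacing > 0), "`spacing` must be positive")
  stop_if_not(background >= 0 && noise_sd >= 0, "background and noise_sd must be >= 0")
  spec <- structure(list(shape = shape, spacing = spacing,
                         background = background, liver = liver,
                         lesions = lesions, exclusions = exclusions,
                         noise_sd = noise_sd, speckle_sd = speckle_sd,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

extent_mm <- function(spec) (spec$shape - 1) * spec$spacing

check_sphere_inside <- function(spec, center, radius, what) {
  ext <- extent_mm(spec)
  if (any(center - radius < 0) || any(center + radius > ext))
    stop(sprintf("%s sphere (center %s, radius %g mm) extends outside the grid (extent %s mm)",
                 what, paste(center, collapse = ","), radius,
                 paste(ext, collapse = "x")), call. = FALSE)
  invisible(TRUE)
}

validate_phantom_spec <- function(spec) {
  liver_r <- 0
  if (!is.null(spec$liver)) {
    liver_r <- (spec$liver$diameter %||% 30) / 2
    check_sphere_inside(spec, spec$liver$center, liver_r, "liver")
    # implied PERCIST threshold from the liver reference plus noise
    sd_tot <- sqrt((spec$liver$sd %||% 0)^2 + spec$noise_sd^2)
    thr <- 1.5 * spec$liver$mean + 2 * sd_tot
    for (les in spec$lesions)
      stop_if_not(les$amplitude > thr,
                  sprintf("lesion amplitude %g does not exceed the implied PERCIST threshold %.3f",
                          les$amplitude, thr))
  }
  for (les in spec$lesions) {
    check_sphere_inside(spec, les$center, les$radius, "lesion")
    if (!is.null(spec$liver)) {
      d <- sqrt(sum((les$center - spec$liver$center)^2))
      stop_if_not(d > les$radius + liver_r,
                  "liver sphere must be disjoint from every lesion")
    }
  }
  for (ex in spec$exclusions)
    check_sphere_inside(spec, ex$center, ex$radius, "exclusion")
  invisible(spec)
}

#' Logical sphere mask on a voxel grid
#'
#' Voxel membership is by voxel-centre distance, inclusive (`<= radius`).
#'
#' @param shape grid shape; @param spacing voxel spacing (mm);
#' @param center sphere centre (mm); @param radius radius (mm);
#' @param origin grid origin (mm).
#' @return logical 3D array.
#' @export
sphere_mask <- function(shape, spacing, center, radius, origin = c(0, 0, 0)) {
  cx <- origin[1] + (seq_len(shape[1]) - 1) * spacing[1]
  cy <- origin[2] + (seq_len(shape[2]) - 1) * spacing[2]
  cz <- origin[3] + (seq_len(shape[3]) - 1) * spacing[3]
  dx2 <- (cx - center[1])^2
  dy2 <- (cy - center[2])^2
  dz2 <- (cz - center[3])^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  d2 <= radius^2 + 1e-9
}

#' Generate a synthetic PET phantom
#'
#' Builds the SUV volume described by a [phantom_spec()]: background, liver
#' sphere (voxel values Gaussian around the liver mean), lesion spheres,
#' then additive Gaussian noise, clipped at zero. Deterministic under the
#' spec's seed.
#'
#' @param spec a `phantom_spec`.
#' @return A list with `volume` (a [suv_volume()]), `lesion_mask` (logical
#'   array, union of lesion spheres), `liver_center` (mm or `NULL`), and
#'   `exclusion_masks` (list of logical arrays).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  with_seed(spec$seed, {
    vol <- array(spec$background, dim = spec$shape)
    if (!is.null(spec$liver)) {
      lm <- sphere_mask(spec$shape, spec$spacing, spec$liver$center,
                        (spec$liver$diameter %||% 30) / 2)
      nl <- sum(lm)
      sdl <- spec$liver$sd %||% 0
      vol[lm] <- spec$liver$mean + if (sdl > 0) rnorm(nl, 0, sdl) else 0
    }
    lesion_mask <- array(FALSE, dim = spec$shape)
    for (les in spec$lesions) {
      m <- sphere_mask(spec$shape, spec$spacing, les$center, les$radius)
      nv <- sum(m)
      vals <- rep(les$amplitude, nv)
      if (identical(les$texture %||% "smooth", "speckled"))
        vals <- vals * exp(rnorm(nv, 0, spec$speckle_sd))
      vol[m] <- vals
      lesion_mask <- lesion_mask | m
    }
    if (spec$noise_sd > 0)
      vol <- vol + rnorm(length(vol), 0, spec$noise_sd)
    vol <- pmax(vol, 0)
    dim(vol) <- spec$shape
    excl <- lapply(spec$exclusions, function(ex)
      sphere_mask(spec$shape, spec$spacing, ex$center, ex$radius))
    list(volume = suv_volume(vol, spacing = spec$spacing),
         lesion_mask = lesion_mask,
         liver_center = if (is.null(spec$liver)) NULL else spec$liver$center,
         exclusion_masks = excl)
  })
}
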