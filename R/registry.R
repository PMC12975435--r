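IMAGE_TYPES <- c("original", "LLL", "LLH", "LHL", "LHH", "HLL", "HLH",
                 "HHL", "HHH")

#' The default radiomic feature registry
#'
#' Ordered identifiers `<image-type>_<class>_<name>` for the full extraction:
#' 93 features (18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
#' 5 NGTDM) on the original image and on each of the 8 coif1 sub-bands
#' (9 x 93 = 837), plus 14 shape features and 5 additional first-order
#' features on the original image only, for a total of 856.
#'
#' @return character vector of class `feature_registry`, length 856.
#' @export
feature_registry <- function() {
  per_image <- function(img) {
    c(paste(img, "firstorder", FIRSTORDER_FEATURES, sep = "_"),
      paste(img, "GLCM", GLCM_FEATURES, sep = "_"),
      paste(img, "GLRLM", GLRLM_FEATURES, sep = "_"),
      paste(img, "GLSZM", GLSZM_FEATURES, sep = "_"),
      paste(img, "GLDM", GLDM_FEATURES, sep = "_"),
      paste(img, "NGTDM", NGTDM_FEATURES, sep = "_"))
  }
  ids <- c(unlist(lapply(IMAGE_TYPES, per_image)),
           paste("original", "shape", SHAPE_FEATURES, sep = "_"),
           paste("original", "firstorder", FIRSTORDER_EXTRA_FEATURES, sep = "_"))
  stopifnot(!anyDuplicated(ids))
  structure(ids, class = c("feature_registry", "character"))
}

#' The three MEL-RAD signature feature identifiers
#'
#' The wavelet texture features retained by the published selection:
#' GLCM cluster prominence on the HLL sub-band and the GLRLM / GLDM
#' gray-level variances on the LHH and HHH sub-bands.
#'
#' @return character vector of length 3.
#' @export
melrad_signature_features <- function() {
  c("HLL_GLCM_ClusterProminence",
    "LHH_GLRLM_GrayLevelVariance",
    "HHH_GLDM_GrayLevelVariance")
}

#' Write / read a feature registry as a plain-text list
#' @param registry a [feature_registry()]; @param path file path.
#' @export
write_registry <- function(registry, path) {
  writeLines(registry, path)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  structure(readLines(path), class = c("feature_registry", "character"))
}

#' Extract the radiomic feature vector of a segmented region
#'
#' Computes every registry feature on the original SUV volume and on each of
#' the eight undecimated coif1 wavelet sub-bands, using the same lesion mask
#' for all image types (the transform is shape-preserving). Each image type
#' is discretized independently with the fixed bin width, anchored at its
#' in-mask minimum. Shape features use the original mask only.
#'
#' @param volume a [suv_volume()] (isotropic spacing expected).
#' @param mask logical 3D array, same grid as `volume`; non-empty.
#' @param registry identifiers to emit, default [feature_registry()].
#' @param width discretization bin width (SUV), default 0.1.
#' @return named numeric vector, `length(registry)` finite values.
#' @export
extract_features <- function(volume, mask, registry = feature_registry(),
                             width = 0.1) {
  stopifnot(inherits(volume, "suv_volume"))
  stop_if_not(identical(dim(volume$data), dim(mask)), "mask/volume mismatch")
  stop_if_not(any(mask), "mask is empty")
  voxel_vol <- prod(volume$spacing)
  bank <- wavelet_decompose(volume)
  images <- c(list(original = volume$data), unclass(bank)[SUBBAND_NAMES])
  out <- numeric(0)
  for (img in IMAGE_TYPES) {
    arr <- images[[img]]
    if (is.null(arr)) stop("missing sub-band: ", img, call. = FALSE)
    region <- discretize_region(arr, mask, width)
    vals <- arr[mask]
    fo <- firstorder_features(vals, voxel_volume = voxel_vol, width = width)
    blocks <- list(firstorder = fo,
                   GLCM = glcm_features(region),
                   GLRLM = glrlm_features(region),
                   GLSZM = glszm_features(region),
                   GLDM = gldm_features(region),
                   NGTDM = ngtdm_features(region))
    for (cls in names(blocks)) {
      v <- blocks[[cls]]
      names(v) <- paste(img, cls, names(v), sep = "_")
      out <- c(out, v)
    }
  }
  sh <- shape_features(mask, volume$spacing)
  names(sh) <- paste("original", "shape", names(sh), sep = "_")
  ex <- firstorder_extra_features(volume$data[mask],
                                  region_volume = sum(mask) * voxel_vol)
  names(ex) <- paste("original", "firstorder", names(ex), sep = "_")
  out <- c(out, sh, ex)
  if (!all(registry %in% names(out)))
    stop("registry identifiers not produced by the extraction: ",
         paste(utils::head(setdiff(registry, names(out)), 3), collapse = ", "),
         call. = FALSE)
  res <- out[registry]
  stop_if_not(all(is.finite(res)), "non-finite feature value produced")
  res
}
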