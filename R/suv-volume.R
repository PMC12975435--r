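#' SUV volume container
#'
#' A `suv_volume` is a 3D grid of standardized uptake values with its voxel
#' spacing in millimetres and a physical origin. Voxel centres sit at
#' `origin + (index - 1) * spacing` on each axis, so the first voxel centre
#' coincides with the origin.
#'
#' @param data numeric 3D array of SUV values (finite, >= 0 for PET data;
#'   wavelet sub-bands relax the non-negativity and use the same container).
#' @param spacing numeric length-3 voxel spacing in mm (all > 0).
#' @param origin numeric length-3 physical position (mm) of the first voxel
#'   centre.
#' @param allow_negative logical; sub-band images may hold negative values.
#' @return An object of class `suv_volume`.
#' @export
suv_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       allow_negative = FALSE) {
  stop_if_not(is.array(data) && length(dim(data)) == 3L,
              "`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stop_if_not(length(spacing) == 3L && all(is.finite(spacing) & spacing > 0),
              "`spacing` must be 3 positive values (mm)")
  stop_if_not(length(origin) == 3L && all(is.finite(origin)),
              "`origin` must be 3 finite values (mm)")
  stop_if_not(all(is.finite(data)), "SUV values must be finite")
  if (!allow_negative)
    stop_if_not(all(data >= 0), "SUV values must be >= 0")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("SUV volume: %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x ")))
  cat(sprintf("  SUV range [%.3f, %.3f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.suv_volume <- function(x) dim(x$data)

#' Physical coordinates (mm) of voxel centres along one axis
#' @keywords internal
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$data)[axis]) - 1) * vol$spacing[axis]
}

#' Read / write SUV volumes and masks as NIfTI
#'
#' Thin wrappers over \pkg{RNifti}. Voxel spacing is carried in the NIfTI
#' pixdim; the origin is kept at the first voxel centre.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume a `suv_volume`.
#' @param mask logical/0-1 3D array.
#' @param spacing voxel spacing for the mask (mm).
#' @return `read_suv_nifti` returns a `suv_volume`; writers return the path.
#' @export
read_suv_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  suv_volume(array(as.numeric(img), dim = dim(img)[1:3]), spacing = sp,
             allow_negative = TRUE)
}

#' @rdname read_suv_nifti
#' @export
write_suv_nifti <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_suv_nifti
#' @export
write_mask_nifti <- function(mask, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname read_suv_nifti
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim = dim(img)[1:3])
}
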