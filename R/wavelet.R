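# Orthogonal coif1 analysis/synthesis filter taps (standard published values).
COIF1_DEC_LO <- c(-0.015655728135791993, -0.07273261951252645,
                  0.3848648468648578, 0.8525720202116004,
                  0.3378976624574818, -0.07273261951252645)
COIF1_DEC_HI <- c(0.07273261951252645, 0.3378976624574818,
                  -0.8525720202116004, 0.3848648468648578,
                  0.07273261951252645, -0.015655728135791993)

SUBBAND_NAMES <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")

# DFT of a centred periodic filter of length n: the output is the circular
# correlation y[i] = sum_k taps[k] x[i + (k-1) - center], i.e. tap index
# `center` is aligned with the output voxel. Wrap-around summing makes axes
# shorter than the filter support well-defined (periodic boundary).
filter_dft <- function(taps, n, center = 2L) {
  kern <- numeric(n)
  for (k in seq_along(taps)) {
    pos <- ((center - (k - 1L)) %% n) + 1L
    kern[pos] <- kern[pos] + taps[k]
  }
  stats::fft(kern)
}

# multiply a 3D spectrum by a separable per-axis transfer function
apply_separable <- function(spec_fft, hx, hy, hz) {
  d <- dim(spec_fft)
  g <- outer(outer(hx, hy), hz)
  dim(g) <- d
  spec_fft * g
}

#' Single-level undecimated 3D coif1 wavelet decomposition
#'
#' Separable stationary (undecimated) wavelet transform with periodic
#' boundary handling, implemented by FFT circular convolution with centred
#' coif1 filters. All eight sub-bands have the same grid shape as the input,
#' so the original lesion mask applies to each sub-band unchanged. Sub-band
#' letters follow array axis order: the first letter is the filter applied
#' along the first array dimension.
#'
#' @param volume a [suv_volume()] or 3D numeric array.
#' @return list of class `wavelet_bank` with elements `LLL`, `LLH`, ...,
#'   `HHH` (3D arrays) and attribute `dim`.
#' @export
wavelet_decompose <- function(volume) {
  arr <- if (inherits(volume, "suv_volume")) volume$data else volume
  stop_if_not(is.array(arr) && length(dim(arr)) == 3L, "need a 3D volume")
  d <- dim(arr)
  f <- stats::fft(arr)
  lo <- lapply(d, function(n) filter_dft(COIF1_DEC_LO, n))
  hi <- lapply(d, function(n) filter_dft(COIF1_DEC_HI, n))
  bank <- lapply(SUBBAND_NAMES, function(nm) {
    ltr <- strsplit(nm, "")[[1]]
    hx <- if (ltr[1] == "L") lo[[1]] else hi[[1]]
    hy <- if (ltr[2] == "L") lo[[2]] else hi[[2]]
    hz <- if (ltr[3] == "L") lo[[3]] else hi[[3]]
    out <- Re(stats::fft(apply_separable(f, hx, hy, hz), inverse = TRUE)) /
      prod(d)
    dim(out) <- d
    out
  })
  names(bank) <- SUBBAND_NAMES
  structure(bank, dim_input = d, class = "wavelet_bank")
}

#' Inverse of [wavelet_decompose()]
#'
#' Exact reconstruction for orthogonal filters: per axis the analysis pair
#' satisfies |L|^2 + |H|^2 = 2, so summing conjugate-filtered sub-bands and
#' dividing by 8 recovers the input.
#'
#' @param bank a `wavelet_bank`.
#' @return 3D numeric array with the original grid shape.
#' @export
wavelet_reconstruct <- function(bank) {
  stopifnot(inherits(bank, "wavelet_bank"))
  d <- attr(bank, "dim_input")
  lo <- lapply(d, function(n) filter_dft(COIF1_DEC_LO, n))
  hi <- lapply(d, function(n) filter_dft(COIF1_DEC_HI, n))
  acc <- array(0 + 0i, dim = d)
  for (nm in SUBBAND_NAMES) {
    ltr <- strsplit(nm, "")[[1]]
    hx <- if (ltr[1] == "L") lo[[1]] else hi[[1]]
    hy <- if (ltr[2] == "L") lo[[2]] else hi[[2]]
    hz <- if (ltr[3] == "L") lo[[3]] else hi[[3]]
    acc <- acc + apply_separable(stats::fft(bank[[nm]]),
                                 Conj(hx), Conj(hy), Conj(hz))
  }
  out <- Re(stats::fft(acc, inverse = TRUE)) / prod(d) / 8
  dim(out) <- d
  out
}

#' @export
print.wavelet_bank <- function(x, ...) {
  d <- attr(x, "dim_input")
  cat(sprintf("coif1 wavelet bank: 8 sub-bands of %d x %d x %d voxels\n",
              d[1], d[2], d[3]))
  invisible(x)
}
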