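test_that("resampling is an identity at the target spacing and exact on constants and ramps", {
  v <- suv_volume(array(runif(6 * 5 * 4), dim = c(6, 5, 4)))
  expect_identical(resample_isotropic(v, 1), v)

  cst <- suv_volume(array(2.5, dim = c(5, 5, 5)), spacing = c(4, 4, 4))
  out <- resample_isotropic(cst, 1)
  expect_equal(out$spacing, c(1, 1, 1))
  expect_true(all(abs(out$data - 2.5) < 1e-12))

  # linear ramp along x: f(x_mm) = 0.5 * x_mm
  d <- c(9, 4, 4)
  ramp <- array(rep(0.5 * (seq_len(d[1]) - 1) * 2, times = prod(d[2:3])), dim = d)
  vr <- suv_volume(ramp, spacing = c(2, 2, 2))
  out <- resample_isotropic(vr, 1)
  expected <- 0.5 * (seq_len(dim(out$data)[1]) - 1) * 1
  expect_lt(max(abs(out$data[, 1, 1] - expected)), 1e-6)
})

test_that("sphere membership uses the inclusive voxel-centre convention", {
  m <- sphere_mask(c(41, 41, 41), c(1, 1, 1), c(20, 20, 20), 15)
  expect_true(m[20 + 15 + 1, 20 + 1, 20 + 1])   # distance exactly 15.0
  expect_false(m[20 + 16 + 1, 20 + 1, 20 + 1])  # distance 16.0 excluded
  # half-voxel spacing puts a centre at exactly 15.5 mm: excluded
  m2 <- sphere_mask(c(81, 81, 81), c(0.5, 0.5, 0.5), c(20, 20, 20), 15)
  expect_true(m2[2 * (20 + 15) + 1, 2 * 20 + 1, 2 * 20 + 1])    # 15.0 mm
  expect_false(m2[2 * 20 + 31 + 1 + 1, 2 * 20 + 1, 2 * 20 + 1]) # 16.0 mm
  expect_false(m2[2 * 20 + 31 + 1, 2 * 20 + 1, 2 * 20 + 1])     # 15.5 mm
})

test_that("liver reference returns mean and population SD by direct enumeration", {
  arr <- array(1.0, dim = c(41, 41, 41))
  vol <- suv_volume(arr)
  m <- sphere_mask(dim(arr), c(1, 1, 1), c(20, 20, 20), 15)
  # constant region
  arr[m] <- 2.0
  ref <- liver_reference(suv_volume(arr), c(20, 20, 20))
  expect_equal(ref$mean, 2.0)
  expect_equal(ref$sd, 0.0)
  expect_equal(ref$n_voxels, sum(m))
  # two-valued region: oracle = direct enumeration of the assigned values
  vals <- rep(c(1, 3), length.out = sum(m))
  arr[m] <- vals
  ref2 <- liver_reference(suv_volume(arr), c(20, 20, 20))
  expect_equal(ref2$mean, mean(vals))
  expect_equal(ref2$sd, sqrt(mean((vals - mean(vals))^2)))
  # sphere partly outside the grid is rejected
  expect_error(liver_reference(suv_volume(arr), c(5, 20, 20)), "outside")
})

test_that("PERCIST threshold follows 1.5 * liver mean + 2 SD and is monotone", {
  ref <- structure(list(mean = 2.0, sd = 0.25), class = "liver_reference")
  expect_equal(percist_threshold(ref), 3.5)
  ref$sd <- 0
  expect_equal(percist_threshold(ref), 3.0)
  expect_gt(percist_threshold(structure(list(mean = 2.1, sd = 0.25),
                                        class = "liver_reference")), 3.5)
  expect_gt(percist_threshold(structure(list(mean = 2.0, sd = 0.3),
                                        class = "liver_reference")), 3.5)
})

test_that("segmentation recovers noiseless lesions exactly and respects exclusions", {
  spec <- phantom_spec(shape = c(40, 40, 40), liver = NULL,
                       lesions = list(list(center = c(20, 20, 20), radius = 6,
                                           amplitude = 8, texture = "smooth")),
                       noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  seg <- segment_lesions(ph$volume, 3.5)
  expect_identical(seg$mask, ph$lesion_mask)
  dice <- 2 * sum(seg$mask & ph$lesion_mask) /
    (sum(seg$mask) + sum(ph$lesion_mask))
  expect_equal(dice, 1.0)
  # idempotence
  seg2 <- segment_lesions(ph$volume, 3.5)
  expect_identical(seg$mask, seg2$mask)
  # an exclusion sphere covering the lesion empties the mask (with warning)
  excl <- sphere_mask(spec$shape, c(1, 1, 1), c(20, 20, 20), 8)
  expect_warning(seg3 <- segment_lesions(ph$volume, 3.5, exclusions = list(excl)),
                 "empty")
  expect_false(any(seg3$mask))
})

test_that("two disjoint lesions give two components with the ground-truth voxel counts", {
  spec <- phantom_spec(shape = c(48, 48, 48), liver = NULL,
                       lesions = list(
                         list(center = c(14, 14, 14), radius = 5,
                              amplitude = 8, texture = "smooth"),
                         list(center = c(34, 34, 34), radius = 6,
                              amplitude = 9, texture = "smooth")),
                       noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  seg <- segment_lesions(ph$volume, 3.5)
  expect_length(seg$component_sizes, 2)
  gt1 <- sum(sphere_mask(spec$shape, c(1, 1, 1), c(14, 14, 14), 5))
  gt2 <- sum(sphere_mask(spec$shape, c(1, 1, 1), c(34, 34, 34), 6))
  expect_setequal(seg$component_sizes, c(gt1, gt2))
  expect_true(all(ph$volume$data[seg$mask] >= 3.5))
})

test_that("components below the minimum size are dropped", {
  arr <- array(1, dim = c(20, 20, 20))
  arr[5, 5, 5] <- 10                     # single hot voxel
  arr[10:13, 10:13, 10:13] <- 10         # 64-voxel block
  seg <- segment_lesions(suv_volume(arr), 5, min_size = 64)
  expect_length(seg$component_sizes, 1)
  expect_equal(seg$component_sizes, 64L)
})

test_that("nifti round trip preserves volumes and masks", {
  ph <- generate_phantom(phantom_spec(shape = c(16, 16, 16), liver = NULL,
                                      lesions = list(), noise_sd = 0.1,
                                      seed = 2))
  f <- tempfile(fileext = ".nii.gz")
  write_suv_nifti(ph$volume, f)
  back <- read_suv_nifti(f)
  expect_equal(back$data, ph$volume$data, tolerance = 1e-6)
  expect_equal(back$spacing, ph$volume$spacing)
  fm <- tempfile(fileext = ".nii.gz")
  m <- sphere_mask(c(16, 16, 16), c(1, 1, 1), c(8, 8, 8), 4)
  write_mask_nifti(m, fm)
  expect_identical(read_mask_nifti(fm), m)
  unlink(c(f, fm))
})
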