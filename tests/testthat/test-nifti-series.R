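test_that("NIfTI round trip preserves data, spacing and axis order", {
  # distinguishable dimensions so axis-order confusion cannot hide
  arr <- array(seq_len(5 * 7 * 9) * 1.5, c(5, 7, 9))
  path <- tempfile(fileext = ".nii")
  write_nifti(arr, path, pixdim = c(1.2, 1.2, 1.0), datatype = "float64")
  nii <- read_nifti(path)
  expect_identical(dim(nii$data), dim(arr))
  expect_equal(nii$data, arr)
  expect_equal(nii$pixdim, c(1.2, 1.2, 1.0), tolerance = 1e-6)
  # the (2, 3, 1) voxel must land where the in-memory array says
  expect_equal(nii$data[2, 3, 1], arr[2, 3, 1])
  # gzipped variant and uint8 masks
  pgz <- tempfile(fileext = ".nii.gz")
  mask <- array(as.integer(runif(5 * 7 * 9) > 0.5), c(5, 7, 9))
  write_nifti(mask, pgz, datatype = "uint8")
  expect_identical(read_nifti(pgz)$data + 0L, mask)
})

test_that("series I/O round-trips and validates input", {
  fr <- array(runif(8 * 6 * 10, 1, 100), c(8, 6, 10))
  s <- perfusion_series(fr, pixel_spacing = c(1.2, 1.2),
                        frame_times = (0:9) * 1.5, slice_level = "mid",
                        condition = "stress", subject_id = "t1")
  path <- tempfile(fileext = ".nii")
  write_series(s, path)
  s2 <- read_series(path, slice_level = "mid", condition = "stress")
  expect_equal(s2$frames, s$frames)
  expect_equal(s2$pixel_spacing, s$pixel_spacing, tolerance = 1e-6)
  expect_equal(s2$frame_times, s$frame_times, tolerance = 1e-6)
  # 2D input rejected with an actionable message
  p2 <- tempfile(fileext = ".nii")
  write_nifti(matrix(1, 4, 4), p2)
  expect_error(read_series(p2), "3D")
  # negative intensities and bad frame times rejected
  expect_error(perfusion_series(array(-1, c(2, 2, 5))), "negative")
  expect_error(perfusion_series(array(1, c(2, 2, 3)),
                                frame_times = c(0, 2, 1)))
})

test_that("series normalization maps to [0,1] and handles degenerate input", {
  fr <- array(100, c(4, 4, 6))
  fr[1, 1, 2] <- 300
  s <- perfusion_series(fr)
  ns <- normalize_series(s)
  expect_equal(min(ns$frames), 0)
  expect_equal(max(ns$frames), 1)
  expect_equal(ns$frames, (fr - 100) / 200)
  # already [0,1] with attained bounds: unchanged
  fr2 <- array(runif(4 * 4 * 6), c(4, 4, 6))
  fr2[1] <- 0; fr2[2] <- 1
  expect_equal(normalize_series(perfusion_series(fr2))$frames, fr2)
  # constant series: all zeros, no division failure
  expect_equal(max(normalize_series(perfusion_series(array(7, c(3, 3, 5))))$frames),
               0)
})
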