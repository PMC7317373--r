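test_that("bounding-box label rule: tight box + margin, clipped", {
  m <- matrix(0L, 256, 256)
  m[101:141, 91:151] <- 1L            # rows 100-140, cols 90-150 (0-based)
  b <- label_bbox_from_mask(m, margin = 20)
  r <- rasterize_box(b, dim(m))
  expect_equal(r$row, c(80, 161))
  expect_equal(r$col, c(70, 171))
  # single pixel, zero margin
  m1 <- matrix(0L, 256, 256); m1[129, 129] <- 1L   # (128,128) 0-based
  b1 <- label_bbox_from_mask(m1, margin = 0)
  expect_equal(b1$center, c(128, 128))
  expect_equal(rasterize_box(b1)$row, c(128, 129))
  # clipping at the image border
  m2 <- matrix(0L, 256, 256); m2[6:21, 100:120] <- 1L   # touches row 5
  expect_equal(rasterize_box(label_bbox_from_mask(m2, 20), dim(m2))$row[1], 0)
  expect_error(label_bbox_from_mask(matrix(0L, 8, 8)), "empty")
})

test_that("centre proposal follows the 75x75 contract", {
  p <- propose_roi(256, 256)
  expect_equal(p$center, c(127.5, 127.5))
  expect_equal(c(p$height, p$width), c(75, 75))
  p2 <- propose_roi(75, 75)
  expect_equal(rasterize_box(p2, c(75, 75)), list(row = c(0, 75),
                                                  col = c(0, 75)))
  expect_equal(propose_roi(100, 200)$center, c(49.5, 99.5))
  expect_error(propose_roi(60, 60), "smaller")
})

test_that("delta transform arithmetic and exact invertibility", {
  prop <- propose_roi(256, 256)
  expect_equal(apply_delta(prop, box_delta(0, 0, 1, 1)), prop)
  b <- apply_delta(prop, box_delta(dx = -5, dy = 10, sw = 0.8, sh = 1.2))
  expect_equal(b$center, c(137.5, 122.5))
  expect_equal(c(b$height, b$width), c(90, 60))
  set.seed(21)
  worst <- 0
  for (i in 1:100) {
    a <- bounding_box(runif(2, 20, 200), runif(1, 10, 120), runif(1, 10, 120))
    target <- bounding_box(runif(2, 20, 200), runif(1, 10, 120),
                           runif(1, 10, 120))
    back <- apply_delta(a, invert_delta(a, target))
    worst <- max(worst, abs(back$center - target$center),
                 abs(back$height - target$height),
                 abs(back$width - target$width))
  }
  expect_lt(worst, 1e-9)
  expect_error(box_delta(sw = 0), "positive")
})

test_that("cropping resamples to 96x96 with rescaled spacing", {
  cfg <- small_config(noise_sd = 0, conditions = "rest",
                      slice_levels = "basal")
  e <- generate_series(cfg, seed = 4)$basal_rest
  # a box of exactly 96x96 is a pure crop
  b96 <- bounding_box(c(63.5, 63.5), 96, 96)
  cs <- crop_series(e$series, b96)
  expect_equal(cs$frames[, , 1], e$series$frames[17:112, 17:112, 1],
               tolerance = 1e-12)
  expect_equal(cs$pixel_spacing, e$series$pixel_spacing)
  # a 75x75 box scales the spacing by 75/96
  b75 <- bounding_box(c(63.5, 63.5), 75, 75)
  cs75 <- crop_series(e$series, b75)
  expect_equal(cs75$pixel_spacing, e$series$pixel_spacing * 75 / 96)
  # masks stay binary under nearest-neighbour cropping
  mk <- crop_mask(e$truth$myo_mask, b75)
  expect_true(all(mk %in% c(0L, 1L)))
  expect_gt(sum(mk), 0)
  # label box rasterized against itself: DSC 1 by construction
  expect_equal(box_dsc(label_bbox_from_mask(e$truth$myo_mask, 20),
                       e$truth$bbox, dim(e$truth$myo_mask)), 1)
})

test_that("crop coordinate transform round-trips", {
  cfg <- small_config(conditions = "rest", slice_levels = "basal")
  e <- generate_series(cfg, seed = 4)$basal_rest
  cs <- crop_series(e$series, e$truth$bbox)
  crop <- attr(cs, "crop")
  set.seed(3)
  for (i in 1:20) {
    p <- runif(2, 0, 95)
    expect_equal(original_to_crop(crop_to_original(p, crop), crop), p,
                 tolerance = 1e-10)
  }
})
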