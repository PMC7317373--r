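test_that("Dice coefficient: trivial cases and the shifted-block example", {
  a <- matrix(0L, 10, 10); a[3:5, 3:5] <- 1L
  expect_equal(dsc(a, a), 1)
  b <- matrix(0L, 10, 10); b[8:9, 8:9] <- 1L
  expect_equal(dsc(a, b), 0)
  # 3x3 block vs the same block shifted one column: overlap 6 px -> 12/18
  s <- matrix(0L, 10, 10); s[3:5, 4:6] <- 1L
  expect_equal(dsc(a, s), 12 / 18)
  expect_equal(dsc(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(dsc(a, matrix(0L, 9, 9)), "shape")
})

test_that("dsc is symmetric and agrees with brute-force counting", {
  set.seed(8)
  for (i in 1:200) {
    a <- matrix(as.integer(runif(144) > runif(1, 0.2, 0.9)), 12, 12)
    b <- matrix(as.integer(runif(144) > runif(1, 0.2, 0.9)), 12, 12)
    expect_identical(dsc(a, b), dsc(b, a))
    expect_equal(dsc(a, b), dsc_bruteforce(a, b))
  }
})

test_that("largest-component postprocessing removes specks", {
  m <- annulus_mask(96, c(47, 47), 14, 22)
  speck <- m
  speck[2:3, 2:3] <- 1L                 # 4-px speck far from the annulus
  expect_identical(largest_component(speck), m)
  expect_identical(largest_component(matrix(0L, 8, 8)), matrix(0L, 8, 8))
})

test_that("closed-loop QC accepts rings, rejects disks and broken arcs", {
  expect_true(qc_closed_loop(annulus_mask(96, c(47, 47), 14, 22)))
  expect_false(qc_closed_loop(disk_mask(96, c(47, 47), 20)))
  expect_false(qc_closed_loop(broken_annulus(96, c(47, 47), 14, 22, 0, 10)))
  expect_false(qc_closed_loop(matrix(0L, 96, 96)))
  # two separate rings: not a single component
  two <- annulus_mask(96, c(25, 25), 8, 12) + annulus_mask(96, c(70, 70), 8, 12)
  expect_false(qc_closed_loop(two))
})

test_that("fallback tries frames by distance, later frame first", {
  fr <- array(runif(96 * 96 * 9), c(96, 96, 9))
  s <- perfusion_series(fr)
  ring <- annulus_mask(96, c(47, 47), 14, 22)
  bad <- disk_mask(96, c(47, 47), 20)
  mask_for <- function(good_frames) {
    function(image, t) if (t %in% good_frames) ring else bad
  }
  # peak passes: no fallback
  r <- segment_with_fallback(s, 4, NULL, segment_fn = mask_for(4))
  expect_equal(r$used_frame, 4L); expect_true(r$passed_qc)
  # peak fails, t+1 passes
  r <- segment_with_fallback(s, 4, NULL, segment_fn = mask_for(5))
  expect_equal(r$used_frame, 5L); expect_true(r$passed_qc)
  # equal distance: later frame (t+1) preferred over t-1
  r <- segment_with_fallback(s, 4, NULL, segment_fn = mask_for(c(3, 5)))
  expect_equal(r$used_frame, 5L)
  # only t-2 passes
  r <- segment_with_fallback(s, 4, NULL, segment_fn = mask_for(2))
  expect_equal(r$used_frame, 2L)
  # all five fail: flagged, peak mask returned
  r <- segment_with_fallback(s, 4, NULL, segment_fn = mask_for(integer()))
  expect_false(r$passed_qc)
  expect_equal(r$used_frame, 4L)
  expect_identical(r$mask, bad)
  # boundary clipping: peak at 0 only tries frames 0..2
  seen <- integer()
  r <- segment_with_fallback(s, 0, NULL, segment_fn = function(img, t) {
    seen <<- c(seen, t); bad
  })
  expect_identical(as.integer(seen), c(0L, 1L, 2L))
})

test_that("Dice loss reduces to 1 - dsc on hard masks", {
  a <- annulus_mask(32, c(15, 15), 5, 9)
  b <- disk_mask(32, c(15, 15), 9)
  logits <- array(ifelse(a == 1, 40, -40), c(32, 32, 1, 1))
  y <- array(b, c(32, 32, 1, 1))
  lo <- perfusionkit:::loss_dice(logits, y)
  expect_equal(lo$loss, 1 - dsc(a, b), tolerance = 1e-5)
})
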