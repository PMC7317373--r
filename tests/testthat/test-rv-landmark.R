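test_that("action-map classes follow the direction-to-landmark rule", {
  map <- build_action_map(c(96, 96), c(50, 50))
  # codes: 1 left, 2 right, 3 up, 4 down (0-based pixel indexing)
  expect_equal(map[51, 11], 2L)   # pixel (50,10): dc = +40 -> right
  expect_equal(map[11, 51], 4L)   # pixel (10,50): dr = +40 -> down
  expect_equal(map[91, 51], 3L)   # below the landmark -> up
  expect_equal(map[51, 91], 1L)   # right of the landmark -> left
  expect_equal(map[51, 51], 2L)   # the landmark pixel itself -> right
  expect_equal(map[41, 41], 2L)   # tie |dr| == |dc| -> horizontal class
  expect_error(build_action_map(c(96, 96), c(96, 40)), "outside")
})

test_that("class pixel counts match exhaustive enumeration", {
  lm <- c(48, 48)
  map <- build_action_map(c(96, 96), lm)
  counts <- tabulate(map, 4)
  oracle <- integer(4)
  for (r in 0:95) {
    for (c in 0:95) {
      dr <- lm[1] - r; dc <- lm[2] - c
      k <- if (abs(dc) > abs(dr)) { if (dc > 0) 2L else 1L }
        else if (abs(dr) > abs(dc)) { if (dr > 0) 4L else 3L }
        else { if (dc >= 0) 2L else 1L }
      oracle[k] <- oracle[k] + 1L
    }
  }
  expect_identical(counts, oracle)
})

test_that("inference recovers the landmark from exact maps", {
  est <- infer_point(build_action_map(c(96, 96), c(48, 48)))
  expect_equal(est$flag, "ok")
  expect_lt(sqrt(sum((est$point - c(48, 48))^2)), 1)
  # grid sweep away from the border
  for (r in c(8, 30, 60, 87)) {
    for (c in c(8, 45, 87)) {
      est <- infer_point(build_action_map(c(96, 96), c(r, c)))
      expect_lt(sqrt(sum((est$point - c(r, c))^2)), 1)
    }
  }
})

test_that("inference is equivariant to translating the map", {
  base <- infer_point(build_action_map(c(96, 96), c(40, 52)))$point
  shifted <- infer_point(build_action_map(c(96, 96), c(47, 49)))$point
  expect_equal(shifted - base, c(7, -3), tolerance = 0.1)
})

test_that("inference tolerates 5% label noise", {
  set.seed(15)
  errs <- numeric(50)
  for (i in 1:50) {
    lm <- runif(2, 12, 83)
    map <- build_action_map(c(96, 96), lm)
    flip <- sample(length(map), round(0.05 * length(map)))
    map[flip] <- sample(1:4, length(flip), replace = TRUE)
    errs[i] <- sqrt(sum((infer_point(map)$point - lm)^2))
  }
  expect_lte(mean(errs), 2)
})

test_that("degenerate maps fall back to the class-centroid heuristic", {
  # landmark on the border: the 'down' class is missing
  map <- build_action_map(c(96, 96), c(95, 48))
  est <- infer_point(map)
  expect_equal(est$flag, "centroid_fallback")
  expect_lt(abs(est$point[2] - 48), 3)
})

test_that("landmark error uses anisotropic spacing in mm", {
  expect_equal(landmark_error_mm(c(10, 20), c(10, 20)), 0)
  expect_equal(landmark_error_mm(c(0, 0), c(3, 4), 1.2), 6)
  expect_equal(landmark_error_mm(c(0, 0), c(1, 1), c(1, 2)), sqrt(5))
})
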