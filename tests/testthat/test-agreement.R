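test_that("Bland-Altman bias and limits of agreement", {
  x <- c(1, 2, 3, 4, 5)
  r <- bland_altman(x, x)
  expect_equal(r$bias, 0)
  expect_equal(c(r$loa_low, r$loa_high), c(0, 0))
  # d = {1,-1,0,2,-2}: bias 0, sd 1.5811, LoA +/- 3.099
  y <- x - c(1, -1, 0, 2, -2)
  r2 <- bland_altman(x, y)
  expect_equal(r2$bias, 0)
  expect_equal(r2$sd_diff, 1.5811, tolerance = 1e-4)
  expect_equal(r2$loa_high, 3.099, tolerance = 1e-3)
  expect_equal(r2$loa_low, -3.099, tolerance = 1e-3)
  # constant offset: bias = c, sd 0
  r3 <- bland_altman(x + 2.5, x)
  expect_equal(r3$bias, 2.5)
  expect_equal(r3$sd_diff, 0)
  # antisymmetry
  set.seed(9)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(bland_altman(a, b)$bias, -bland_altman(b, a)$bias)
  expect_error(bland_altman(1:2, 1:2), "3")
})

test_that("ICC(2,1) matches a from-scratch two-way ANOVA", {
  x <- c(1, 2, 3, 4, 5, 6) + 0.1
  expect_equal(icc_agreement(x, x)$icc, 1, tolerance = 1e-12)
  # oracle: MS terms from stats::aov on the long-format two-way layout
  icc_oracle <- function(x, y) {
    n <- length(x)
    d <- data.frame(score = c(x, y),
                    subj = factor(rep(seq_len(n), 2)),
                    rater = factor(rep(1:2, each = n)))
    ms <- summary(stats::aov(score ~ subj + rater, data = d))[[1]][["Mean Sq"]]
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
  }
  set.seed(12)
  for (i in 1:20) {
    n <- sample(6:50, 1)
    subj <- rnorm(n, 2, 1)
    x <- subj + rnorm(n, 0, 0.3)
    y <- subj + rnorm(n, 0.1, 0.3)
    r <- icc_agreement(x, y)
    expect_equal(r$icc, icc_oracle(x, y), tolerance = 1e-10)
    expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
    # rater exchange invariance
    expect_equal(icc_agreement(y, x)$icc, r$icc, tolerance = 1e-12)
  }
  # absolute agreement penalizes a constant offset
  base <- rnorm(30, 5, 2)
  expect_lt(icc_agreement(base, base + 4)$icc, 0.6)
  expect_error(icc_agreement(1:4, 1:4), "5")
  expect_error(icc_agreement(rep(1, 10), rep(1, 10)), "variance")
})

test_that("through-origin regression slope and no-intercept R2", {
  x <- c(1, 2, 3, 4)
  expect_equal(slope_through_origin(x, x), list(slope = 1, r2 = 1, n = 4))
  expect_equal(slope_through_origin(x, 2 * x)$slope, 2)
  expect_equal(slope_through_origin(x, 2 * x)$r2, 1)
  r <- slope_through_origin(c(1, 2, 3), c(2, 3, 7))
  expect_equal(r$slope, 29 / 14, tolerance = 1e-12)
  # cross-check against lm with a suppressed intercept
  set.seed(13)
  a <- runif(25, 0.5, 3); b <- 0.9 * a + rnorm(25, 0, 0.2)
  fit <- stats::lm(b ~ a + 0)
  rr <- slope_through_origin(a, b)
  expect_equal(rr$slope, unname(coef(fit)), tolerance = 1e-12)
  expect_equal(rr$r2, 1 - sum(residuals(fit)^2) / sum(b^2), tolerance = 1e-12)
  expect_error(slope_through_origin(c(0, 0), c(1, 2)), "zero")
})
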