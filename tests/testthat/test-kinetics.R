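make_aif <- function(n = 50) {
  t <- seq(0, n - 1)
  concentration_curve(t, gamma_variate_aif(10, 2.5, 3, 5, t))
}

test_that("2CXM forward model: analytic limits", {
  aif <- make_aif()
  # no delivery
  expect_equal(solve_2cxm(kinetic_params(0, 0.05, 0.5, 0.2), aif)$values,
               rep(0, 50))
  # PS = 0, constant input: steady state vp * c0
  const <- concentration_curve(seq(0, 599), rep(2, 600))
  ct <- solve_2cxm(kinetic_params(1, 0.1, 0, 0.2), const)
  expect_equal(tail(ct$values, 1), 0.1 * 2, tolerance = 1e-6)
  expect_error(kinetic_params(-1, 0.05, 0.5, 0.2), "non-negative")
})

test_that("analytic convolution agrees with stiff ODE integration", {
  aif <- make_aif()
  set.seed(30)
  for (i in 1:4) {
    p <- kinetic_params(runif(1, 0.3, 3), runif(1, 0.03, 0.2),
                        runif(1, 0.2, 2), runif(1, 0.1, 0.5))
    ct <- solve_2cxm(p, aif)
    ref <- rk4_2cxm(p, aif$values, aif$times)
    expect_lt(max(abs(ct$values - ref)), 1e-4)
    # the C++ fast path used inside fitting matches the reference solver
    fast <- cxm_tissue_cpp(p$Fp, p$vp, p$PS, p$ve, aif$values, aif$times)
    expect_lt(max(abs(fast - ct$values)), 1e-10)
  }
})

test_that("2CXM is linear in the AIF and homogeneous in amplitude", {
  t <- seq(0, 49)
  a1 <- concentration_curve(t, gamma_variate_aif(8, 2, 2.5, 4, t))
  a2 <- concentration_curve(t, gamma_variate_aif(14, 3, 2, 3, t))
  p <- kinetic_params(1.2, 0.06, 0.8, 0.25)
  sum_in <- concentration_curve(t, a1$values + a2$values)
  expect_equal(solve_2cxm(p, sum_in)$values,
               solve_2cxm(p, a1)$values + solve_2cxm(p, a2)$values,
               tolerance = 1e-12)
  scaled <- concentration_curve(t, 3.5 * a1$values)
  expect_equal(solve_2cxm(p, scaled)$values, 3.5 * solve_2cxm(p, a1)$values,
               tolerance = 1e-12)
})

test_that("signal-to-concentration conversion", {
  expect_equal(signal_to_conc(rep(4, 10))$values, rep(0, 10))
  expect_equal(signal_to_conc(c(2, 2, 2, 2, 2, 3), baseline_frames = 5)$values[6],
               0.5)
  expect_error(signal_to_conc(rep(0, 10)), "positive")
  expect_error(signal_to_conc(c(1, 2), baseline_frames = 5))
})

test_that("model fitting recovers noiseless parameters", {
  aif <- make_aif()
  truth <- kinetic_params(1.3, 0.07, 0.9, 0.22)
  ct <- solve_2cxm(truth, aif)
  # initialized at the truth: fixed point
  f0 <- fit_2cxm(ct, aif, start = truth)
  expect_equal(f0$params$Fp, truth$Fp, tolerance = 1e-4)
  expect_lt(f0$residual_norm, 1e-6)
  # multi-start recovery of Fp for random parameter sets
  set.seed(31)
  for (i in 1:5) {
    p <- kinetic_params(runif(1, 0.4, 3), runif(1, 0.03, 0.15),
                        runif(1, 0.3, 1.8), runif(1, 0.1, 0.4))
    fit <- fit_2cxm(solve_2cxm(p, aif), aif)
    expect_lt(abs(fit$params$Fp - p$Fp) / p$Fp, 0.01)
  }
  expect_error(fit_2cxm(concentration_curve(aif$times, aif$values * NA_real_),
                        aif))
})

test_that("voxelwise fitting maps a small region accurately", {
  aif <- make_aif()
  set.seed(32)
  H <- 8; W <- 8
  mask <- matrix(1L, H, W)
  truth_fp <- matrix(runif(H * W, 0.5, 2.5), H, W)
  conc <- array(0, c(H, W, 50))
  for (v in 1:(H * W)) {
    p <- kinetic_params(truth_fp[v], 0.06, 1.0, 0.2)
    conc[((1:50) - 1) * H * W + v] <- solve_2cxm(p, aif)$values
  }
  maps <- fit_2cxm_map(conc, aif, mask)
  expect_lt(median(abs(maps$Fp - truth_fp) / truth_fp), 0.02)
})

test_that("AIF extraction: region growth and phantom containment", {
  # uniform pool: the region is the whole connected interior
  n <- 64
  myo <- annulus_mask(n, c(31, 31), 10, 16)
  interior <- interior_from_mask(myo)
  fr <- array(1, c(n, n, 10))
  for (t in 1:10) fr[, , t][interior == 1] <- 10 + t
  s <- perfusion_series(fr)
  res <- extract_aif(s, interior, peak = 5)
  expect_identical(res$region, interior)
  expect_error(extract_aif(s, matrix(0L, n, n), 5), "empty")

  # phantom: the seed voxel lies inside the true LV pool
  cfg <- small_config(conditions = "rest", slice_levels = "basal")
  hits <- 0
  for (i in 1:25) {
    e <- generate_series(cfg, seed = 400 + i)$basal_rest
    interior <- interior_from_mask(e$truth$myo_mask)
    res <- extract_aif(e$series, interior, e$truth$peak_frame)
    hits <- hits + e$truth$lv_pool_mask[res$seed[1] + 1, res$seed[2] + 1]
  }
  expect_equal(hits, 25)
})

test_that("noiseless phantom AIF extraction is exact on the native grid", {
  cfg <- small_config(noise_sd = 0, conditions = "rest",
                      slice_levels = "basal")
  e <- generate_series(cfg, seed = 41)$basal_rest
  interior <- interior_from_mask(e$truth$myo_mask)
  res <- extract_aif(e$series, interior, e$truth$peak_frame,
                     gamma = cfg$signal_gain)
  expect_lt(max(abs(res$aif$values - e$truth$aif_true$values)), 1e-6)
})

test_that("AHA division partitions the mask with the right sector counts", {
  myo <- annulus_mask(128, c(63.5, 63.5), 18, 26)
  ctr <- c(63.5, 63.5)
  pts <- list(
    anterior = c(ctr[1] - 26 * sin(120 * pi / 180),
                 ctr[2] + 26 * cos(120 * pi / 180)),
    inferior = c(ctr[1] - 26 * sin(240 * pi / 180),
                 ctr[2] + 26 * cos(240 * pi / 180)))
  lab_b <- aha_divide(myo, pts, "basal")
  lab_m <- aha_divide(myo, pts, "mid")
  lab_a <- aha_divide(myo, pts, "apical")
  expect_setequal(unique(lab_b[lab_b > 0]), 1:6)
  expect_setequal(unique(lab_m[lab_m > 0]), 7:12)
  expect_setequal(unique(lab_a[lab_a > 0]), 13:16)
  # labels partition the mask exactly
  expect_true(all((lab_b > 0) == (myo == 1)))
  # sector counts match brute-force angle binning about the centroid
  idx <- which(myo == 1, arr.ind = TRUE)
  cen <- c(mean(idx[, 1]) - 1, mean(idx[, 2]) - 1)
  th <- (atan2(-(idx[, 1] - 1 - cen[1]), idx[, 2] - 1 - cen[2]) * 180 / pi) %% 360
  th_a <- (atan2(-(pts$anterior[1] - cen[1]),
                 pts$anterior[2] - cen[2]) * 180 / pi) %% 360
  rel <- ((th - th_a) %% 360 + 360) %% 360
  brute <- tabulate(floor(rel / 60) + 1, 6)
  expect_identical(as.integer(tabulate(lab_b[lab_b > 0], 6)), as.integer(brute))
  expect_error(aha_divide(myo, list(anterior = c(1, 1), inferior = c(1, 1)),
                          "basal"), "distinct")
})

test_that("per-segment MBF aggregation", {
  myo <- annulus_mask(96, c(47.5, 47.5), 14, 22)
  pts <- list(anterior = c(28, 36), inferior = c(67, 36))
  lab <- aha_divide(myo, pts, "basal")
  fp <- matrix(NA_real_, 96, 96); fp[myo == 1] <- 1.0
  tab <- per_segment_mbf(fp, lab)
  expect_equal(tab$mean_mbf, rep(1, 6))
  # locality: bump one segment only
  fp2 <- fp; fp2[lab == 3] <- 2.0
  tab2 <- per_segment_mbf(fp2, lab)
  expect_equal(tab2$mean_mbf[tab2$segment == 3], 2)
  expect_equal(tab2$mean_mbf[tab2$segment != 3], rep(1, 5))
  # grouping matches brute force to near machine precision
  fp3 <- fp; fp3[myo == 1] <- runif(sum(myo), 0.5, 3)
  tab3 <- per_segment_mbf(fp3, lab)
  for (s in 1:6)
    expect_equal(tab3$mean_mbf[tab3$segment == s], mean(fp3[lab == s]),
                 tolerance = 1e-12)
  # empty segments reported as missing, not zero
  tab4 <- per_segment_mbf(fp, lab, expected_segments = 1:7)
  expect_true(is.na(tab4$mean_mbf[tab4$segment == 7]))
  expect_equal(tab4$n_voxels[tab4$segment == 7], 0)
})
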