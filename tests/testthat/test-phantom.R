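test_that("gamma-variate bolus: pre-arrival zero, analytic peak, linearity", {
  times <- seq(0, 60, by = 0.05)
  expect_equal(gamma_variate_aif(10, 2.5, 3, 5, c(0, 5, 10)), c(0, 0, 0))
  cur <- gamma_variate_aif(10, 2.5, 3, 5, times)
  expect_lt(abs(times[which.max(cur)] - (10 + 2.5 * 3)), 0.051)
  expect_equal(max(cur), 5, tolerance = 1e-4)  # scale is the peak value
  set.seed(42)
  for (i in 1:10) {
    t0 <- runif(1, 0, 15); al <- runif(1, 0.5, 5)
    be <- runif(1, 0.5, 5); sc <- runif(1, 0.1, 10)
    a1 <- gamma_variate_aif(t0, al, be, sc, times)
    a2 <- gamma_variate_aif(t0, al, be, 2 * sc, times)
    expect_true(all(is.finite(a1)) && all(a1 >= 0))
    expect_equal(a2, 2 * a1, tolerance = 1e-12)
  }
  expect_error(gamma_variate_aif(0, -1, 3, 5, times), "positive")
  expect_error(gamma_variate_aif(0, 2, 0, 5, times), "positive")
})

test_that("rendered geometry matches analytic areas and insertion angles", {
  cfg <- exact_config(r_pool = 20, thickness = 10)
  set.seed(7)
  g <- render_geometry(cfg, "basal")
  expect_equal(sum(g$myo_mask), pi * (30^2 - 20^2), tolerance = 0.05)
  # insertion points within 1 px of the analytic circle positions
  ctr <- g$centre
  for (nm in c("anterior", "inferior")) {
    th <- if (nm == "anterior") 120 else 240
    analytic <- c(ctr[1] - 30 * sin(th * pi / 180),
                  ctr[2] + 30 * cos(th * pi / 180))
    expect_lt(sqrt(sum((g$insertion_points[[nm]] - analytic)^2)), 1 + 1e-9)
  }
  expect_true(qc_closed_loop(g$myo_mask))
})

test_that("geometry invariants hold across random configurations", {
  cfg <- small_config()
  set.seed(11)
  for (i in 1:20) {
    slice <- sample(c("basal", "mid", "apical"), 1)
    g <- render_geometry(cfg, slice)
    # masks pairwise disjoint
    expect_equal(max(g$myo_mask + g$lv_pool_mask + g$rv_mask), 1)
    # myocardium: one 4-connected component enclosing the pool
    expect_true(qc_closed_loop(g$myo_mask))
    interior <- interior_from_mask(g$myo_mask)
    expect_true(all(interior[g$lv_pool_mask == 1] == 1))
    # insertion points sit on the epicardial rim
    for (p in g$insertion_points) {
      expect_equal(g$myo_mask[p[1] + 1, p[2] + 1], 1L)
      d <- sqrt(sum((p - g$centre)^2))
      expect_lt(abs(d - g$r_epi), 1.5)
    }
  }
})

test_that("series generation is reproducible and truth is self-consistent", {
  cfg <- small_config(noise_sd = 0)
  s1 <- generate_series(cfg, seed = 5)
  s2 <- generate_series(cfg, seed = 5)
  expect_identical(s1, s2)
  e <- s1$basal_rest
  # zero noise, zero motion: recorded peak equals the LV-pool signal argmax
  pool_sig <- apply(e$series$frames, 3,
                    function(fr) mean(fr[e$truth$lv_pool_mask == 1]))
  expect_identical(which.max(pool_sig) - 1L, e$truth$peak_frame)
  # first-pass ordering: RV peak < LV peak < myocardial peak
  myo_sig <- apply(e$series$frames, 3,
                   function(fr) mean(fr[e$truth$myo_mask == 1]))
  expect_lt(which.max(e$truth$rv_curve$values), which.max(pool_sig))
  expect_lt(which.max(pool_sig), which.max(myo_sig))
  expect_error(small_config(n_frames = 4), "n_frames")
})

test_that("noiseless phantom inverts exactly through signal_to_conc", {
  cfg <- small_config(noise_sd = 0, conditions = "rest",
                      slice_levels = "mid")
  e <- generate_series(cfg, seed = 9)$mid_rest
  # LV pool voxel -> generating AIF
  vox <- which(e$truth$lv_pool_mask == 1)[1]
  sig <- e$series$frames[(seq_len(cfg$n_frames) - 1) * cfg$image_size^2 + vox]
  cc <- signal_to_conc(sig, e$series$frame_times, baseline_frames = 5,
                       gamma = cfg$signal_gain)
  expect_lt(max(abs(cc$values - e$truth$aif_true$values)), 1e-6)
  # myocardial voxel -> its generating 2CXM curve
  mv <- which(e$truth$myo_mask == 1)[10]
  p <- kinetic_params(e$truth$param_maps$Fp[mv], e$truth$param_maps$vp[mv],
                      e$truth$param_maps$PS[mv], e$truth$param_maps$ve[mv])
  ct_true <- solve_2cxm(p, e$truth$aif_true)
  sigm <- e$series$frames[(seq_len(cfg$n_frames) - 1) * cfg$image_size^2 + mv]
  ccm <- signal_to_conc(sigm, e$series$frame_times, baseline_frames = 5,
                        gamma = cfg$signal_gain)
  expect_lt(max(abs(ccm$values - ct_true$values)), 1e-6)
})

test_that("stress kinetics raise peak myocardial concentration above rest", {
  cfg <- small_config(noise_sd = 0, slice_levels = "mid")
  higher <- 0
  n_subj <- 50
  for (i in seq_len(n_subj)) {
    s <- generate_series(cfg, seed = 1000 + i)
    peak_conc <- function(e) {
      myo <- e$truth$myo_mask == 1
      sig <- apply(e$series$frames, 3, function(fr) mean(fr[myo]))
      max(signal_to_conc(sig, e$series$frame_times, 5,
                         cfg$signal_gain)$values)
    }
    if (peak_conc(s$mid_stress) > peak_conc(s$mid_rest)) higher <- higher + 1
  }
  expect_gte(higher / n_subj, 0.95)
})

test_that("phantom subjects round-trip through the on-disk layout", {
  cfg <- small_config(conditions = "rest", slice_levels = "basal")
  subj <- generate_series(cfg, seed = 3)
  dir <- tempfile("phantom")
  write_phantom(subj, dir)
  expect_true(file.exists(file.path(dir, "basal_rest.nii.gz")))
  s <- read_series(file.path(dir, "basal_rest.nii.gz"))
  expect_equal(dim(s$frames), dim(subj$basal_rest$series$frames))
  expect_equal(s$pixel_spacing, subj$basal_rest$series$pixel_spacing,
               tolerance = 1e-6)
  expect_equal(s$frames, subj$basal_rest$series$frames, tolerance = 1e-5)
  truth <- jsonlite::read_json(file.path(dir, "basal_rest_truth.json"))
  expect_equal(truth$peak_frame, subj$basal_rest$truth$peak_frame)
  aif <- read.csv(file.path(dir, "basal_rest_aif.csv"))
  expect_equal(aif$concentration, subj$basal_rest$truth$aif_true$values)
})
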