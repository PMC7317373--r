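test_that("default configuration echoes the published hyperparameters", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 32)
  expect_equal(cfg$learning_rate, 1e-4)
  expect_equal(cfg$l2_weight, 0.001)
  expect_equal(cfg$dropout_p, 0.5)
  expect_equal(cfg$patience, 3000)
})

test_that("augmentation: identity ranges, exact translation, determinism", {
  img <- matrix(runif(96 * 96), 96, 96)
  mask <- annulus_mask(96, c(47, 47), 10, 16)
  zero <- augment_ranges(0, 0, 0, 0, 0)
  out <- augment(img, mask, zero, label_type = "mask")
  expect_equal(out$image, img)
  expect_identical(out$label, mask)
  # pure translation +5 rows (the transform augment() applies) moves the
  # mask centroid by exactly +5 rows
  cen <- function(m) colMeans(which(m == 1, arr.ind = TRUE))
  M5 <- cbind(diag(2), c(-5, 0))         # output -> input map for +5 rows
  m5 <- warp_affine(mask, M5, "nearest")
  expect_equal(cen(m5) - cen(mask), c(5, 0), ignore_attr = TRUE)
  # random translation: mask centroid tracks the drawn shift
  tr_only <- augment_ranges(translate = 5, rotate = 0, scale = 0,
                            intensity = 0, noise = 0)
  set.seed(104)
  probe <- runif(2, -5, 5)
  set.seed(104)
  out <- augment(img, mask, tr_only, label_type = "mask")
  # nearest-neighbour warping quantizes a pure translation to integer shifts
  expect_equal(cen(out$label) - cen(mask), round(probe), ignore_attr = TRUE)
  # points transform matches the coordinate map
  set.seed(7)
  p_out <- augment(img, c(40, 50), tr_only, label_type = "points")
  set.seed(7)
  shift <- runif(2, -5, 5)
  expect_equal(p_out$label, c(40, 50) + shift, tolerance = 1e-9)
  # same seed, same result
  set.seed(5); a1 <- augment(img, mask, augment_ranges(), "mask")
  set.seed(5); a2 <- augment(img, mask, augment_ranges(), "mask")
  expect_identical(a1, a2)
  expect_true(all(a1$image >= 0 & a1$image <= 1))
})

test_that("L2 decay applies to convolution kernels only", {
  model <- nn_init(arch_spec("unet_seg", in_size = 16, base_filters = 3,
                             levels = 2), seed = 1)
  expect_true(all(grepl("_w$", model$decay_params)))
  expect_false(any(grepl("bn", model$decay_params)))
  expect_false(any(grepl("_b$", model$decay_params)))
  # every non-decayed parameter is a bias or batch-norm parameter
  others <- setdiff(names(model$params), model$decay_params)
  expect_true(all(grepl("(_b|_bng|_bnb)$", others)))
  model2 <- nn_init(arch_spec("classifier_cnn", in_channels = 1,
                              in_size = 16, conv_widths = c(2, 3, 4, 5),
                              fc_width = 6), seed = 1)
  expect_false(any(grepl("^fc", model2$decay_params)))
  expect_equal(sum(grepl("^conv", model2$decay_params)), 4)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(3)
  arch <- arch_spec("classifier_cnn", in_channels = 2, in_size = 16,
                    conv_widths = c(3, 4, 5, 6), fc_width = 7)
  model <- nn_init(arch, seed = 4)
  x <- array(runif(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  y <- c(1L, 2L, 1L)
  fw <- nn_forward(model, x, train = TRUE)
  lo <- perfusionkit:::loss_softmax_ce(fw$out, y)
  gr <- nn_backward(model, fw$cache, lo$dout)
  lossfn <- function(params) {
    m <- model; m$params <- params
    perfusionkit:::loss_softmax_ce(nn_forward(m, x, train = TRUE)$out, y)$loss
  }
  for (nm in c("conv1_w", "conv2_bng", "fc1_w", "fc2_b")) {
    p <- model$params[[nm]]
    idx <- sample(length(p), min(4, length(p)))
    for (j in idx) {
      eps <- 1e-5
      p1 <- model$params; p1[[nm]][j] <- p[j] + eps
      p2 <- model$params; p2[[nm]][j] <- p[j] - eps
      ng <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      expect_equal(gr[[nm]][j], ng, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and early stopping obeys patience", {
  set.seed(6)
  # tiny segmentation problem: 4 samples, overfit sanity
  side <- 32
  x <- array(0, c(side, side, 1, 4))
  y <- array(0, c(side, side, 1, 4))
  for (i in 1:4) {
    m <- annulus_mask(side, c(14 + i, 14 + i), 5, 9)
    x[, , 1, i] <- m * 0.8 + matrix(runif(side^2, 0, 0.1), side)
    y[, , 1, i] <- m
  }
  cfg <- train_config(batch_size = 4, learning_rate = 3e-3, patience = 400,
                      max_iter = 150, eval_every = 25, dropout_p = 0,
                      augment = NULL, seed = 2)
  arch <- arch_spec("unet_seg", in_size = side, base_filters = 4, levels = 2)
  m <- train_model(arch, list(x = x, y = y), list(x = x, y = y), cfg)
  first_losses <- head(m$log$train_loss, 10)
  dices <- sapply(1:4, function(i) dsc(segment_frame(x[, , 1, i], m),
                                       y[, , 1, i]))
  expect_gte(mean(dices), 0.95)
  expect_lt(m$best_val, mean(first_losses))

  # frozen optimisation (lr = 0): stops right after patience runs out
  cfg0 <- train_config(batch_size = 4, learning_rate = 0, patience = 5,
                       max_iter = 500, eval_every = 1, dropout_p = 0,
                       augment = NULL, seed = 2)
  m0 <- train_model(arch, list(x = x, y = y), list(x = x, y = y), cfg0)
  expect_lte(max(m0$log$iter), 5 + 2)
  expect_error(train_model(arch, list(x = NULL, y = NULL),
                           list(x = x, y = y), cfg0), "empty")
})

test_that("checkpoints round-trip through save/load", {
  arch <- arch_spec("bbox_cnn", in_channels = 1, in_size = 16,
                    conv_widths = c(2, 2, 3, 3), fc_width = 4)
  m <- nn_init(arch, seed = 9)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$params, m$params)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  expect_equal(nn_forward(m2, x)$out, nn_forward(m, x)$out)
})
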