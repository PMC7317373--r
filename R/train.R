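## Training harness: configuration (published hyperparameters as defaults, a
## desk-scale profile for CPU-budget experiments), on-the-fly augmentation,
## loss functions per architecture, Adam with L2 on convolution kernels only,
## and early stopping on the validation metric.

#' Augmentation ranges
#'
#' All ranges are symmetric about the identity transform; a value of zero
#' disables that component.
#'
#' @param translate max |translation| in pixels (each axis).
#' @param rotate max |rotation| in degrees.
#' @param scale max |scale - 1|.
#' @param intensity max |gain - 1| multiplicative intensity variation.
#' @param noise max additive Gaussian noise sd (intensity units, post
#'   normalization).
#' @return list of ranges.
#' @export
augment_ranges <- function(translate = 4, rotate = 8, scale = 0.08,
                           intensity = 0.1, noise = 0.02) {
  list(translate = translate, rotate = rotate, scale = scale,
       intensity = intensity, noise = noise)
}

#' Training configuration
#'
#' Defaults are the published hyperparameters: batch size 32, Adam with
#' learning rate 1e-4, L2 weight 0.001 on convolution kernels only, dropout
#' 0.5 in the fully-connected layers, early stopping with a patience of 3000
#' iterations. The `"desk"` preset scales the iteration budget down for
#' CPU-scale synthetic experiments (hyperparameter values, not contracts).
#'
#' @param batch_size samples per iteration.
#' @param learning_rate Adam step size.
#' @param l2_weight L2 penalty weight, applied to conv kernels only.
#' @param patience early-stopping patience in iterations.
#' @param dropout_p dropout probability in fully-connected layers.
#' @param augment an [augment_ranges()] list, or NULL to disable.
#' @param max_iter iteration budget.
#' @param eval_every validation interval in iterations.
#' @param seed RNG seed for initialisation, batching, dropout, augmentation.
#' @param preset "published" (defaults as stated) or "desk" (small budget).
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, learning_rate = 1e-4,
                         l2_weight = 0.001, patience = 3000,
                         dropout_p = 0.5, augment = augment_ranges(),
                         max_iter = 30000, eval_every = 100, seed = 1,
                         preset = c("published", "desk")) {
  preset <- match.arg(preset)
  cfg <- as.list(environment())
  if (preset == "desk") {
    supplied <- names(match.call())[-1]
    desk <- list(batch_size = 16, learning_rate = 1e-3, patience = 150,
                 max_iter = 350, eval_every = 25,
                 augment = augment_ranges(translate = 3, rotate = 5,
                                          scale = 0.05, intensity = 0.08,
                                          noise = 0.02))
    for (nm in setdiff(names(desk), supplied)) cfg[[nm]] <- desk[[nm]]
  }
  stopifnot(cfg$batch_size >= 1)
  structure(cfg, class = "train_config")
}

#' Apply a random spatial + intensity augmentation to an image and label
#'
#' Draws translation, rotation, scaling, intensity gain and noise uniformly
#' within `ranges` (using the current RNG state, hence seeded reproducibly)
#' and applies the same spatial transform to the image stack and its label:
#' masks via nearest-neighbour warping, points and boxes via the coordinate
#' transform. Intensities are clipped to [0, 1].
#'
#' @param image matrix or `[H, W, C]` array in [0, 1].
#' @param label NULL, a binary mask matrix, a 0-based (row, col) point (or
#'   list of points), or a [bounding_box()] (boxes ignore rotation).
#' @param ranges an [augment_ranges()] list.
#' @param label_type one of "none", "mask", "points", "box".
#' @return list `(image, label)` after augmentation.
#' @export
augment <- function(image, label = NULL, ranges = augment_ranges(),
                    label_type = c("none", "mask", "points", "box")) {
  label_type <- match.arg(label_type)
  was_mat <- is.matrix(image)
  if (was_mat) image <- array(image, c(dim(image), 1))
  H <- dim(image)[1]; W <- dim(image)[2]
  tr <- runif(2, -ranges$translate, ranges$translate)
  th <- runif(1, -ranges$rotate, ranges$rotate) * pi / 180
  sc <- 1 + runif(1, -ranges$scale, ranges$scale)
  gain <- 1 + runif(1, -ranges$intensity, ranges$intensity)
  nsd <- runif(1, 0, ranges$noise)
  ctr <- c((H - 1) / 2, (W - 1) / 2)
  A <- sc * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  identity_tf <- all(tr == 0) && th == 0 && sc == 1
  if (!identity_tf) {
    Ai <- solve(A)
    M <- cbind(Ai, ctr - Ai %*% (ctr + tr))
    for (c_ in seq_len(dim(image)[3]))
      image[, , c_] <- warp_affine(image[, , c_], M, "bilinear")
    label <- switch(label_type,
      none = label,
      mask = warp_affine(label, M, "nearest"),
      points = {
        pts <- if (is.list(label)) label else list(label)
        out <- lapply(pts, function(p) as.double(A %*% (p - ctr) + ctr + tr))
        if (is.list(label)) out else out[[1]]
      },
      box = bounding_box(center = as.double(label$center - ctr) * sc +
                           ctr + tr,
                         height = label$height * sc,
                         width = label$width * sc))
  }
  if (gain != 1 || nsd > 0) {
    image <- image * gain
    if (nsd > 0) image <- image + array(rnorm(length(image), 0, nsd),
                                        dim(image))
    image <- clamp(image, 0, 1)
  }
  if (was_mat) image <- image[, , 1]
  list(image = image, label = label)
}

## ---- losses --------------------------------------------------------------

.softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

## classifier: logits [K, N], y integer class in 1..K
loss_softmax_ce <- function(logits, y) {
  p <- .softmax_cols(logits)
  n <- ncol(logits)
  ll <- -mean(log(pmax(p[cbind(y, seq_len(n))], 1e-12)))
  dp <- p
  dp[cbind(y, seq_len(n))] <- dp[cbind(y, seq_len(n))] - 1
  list(loss = ll, dout = dp / n)
}

## bbox regression: pred [4, N], y [4, N]
loss_mse <- function(pred, y) {
  d <- pred - y
  list(loss = mean(d^2), dout = 2 * d / length(d))
}

## segmentation: logits [H, W, 1, N], y [H, W, 1, N] in {0,1}; soft Dice
loss_dice <- function(logits, y, eps = 1e-6) {
  p <- 1 / (1 + exp(-logits))
  N <- dim(logits)[4]
  loss <- 0
  dout <- array(0, dim(logits))
  for (n in seq_len(N)) {
    pn <- p[, , 1, n]; gn <- y[, , 1, n]
    num <- 2 * sum(pn * gn) + eps
    den <- sum(pn) + sum(gn) + eps
    loss <- loss + (1 - num / den)
    dldp <- -(2 * gn * den - num) / den^2
    dout[, , 1, n] <- dldp * pn * (1 - pn) / N
  }
  list(loss = loss / N, dout = dout)
}

## action maps: logits [H, W, K, N], y [H, W, N] integer class 1..K
loss_pixel_ce <- function(logits, y) {
  d <- dim(logits)
  K <- d[3]
  zm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = K)  # (H*W*N) x K
  zm <- zm - apply(zm, 1, max)
  e <- exp(zm)
  p <- e / rowSums(e)
  yi <- as.integer(y)
  M <- nrow(p)
  ll <- -mean(log(pmax(p[cbind(seq_len(M), yi)], 1e-12)))
  dp <- p
  dp[cbind(seq_len(M), yi)] <- dp[cbind(seq_len(M), yi)] - 1
  dout <- aperm(array(dp / M, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
  list(loss = ll, dout = dout)
}

loss_for_kind <- function(kind) {
  switch(kind,
         classifier_cnn = loss_softmax_ce,
         bbox_cnn = loss_mse,
         unet_seg = loss_dice,
         unet_action = loss_pixel_ce)
}

## ---- optimiser -----------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, opt, lr, l2, decay_names,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (nm %in% decay_names) g <- g + l2 * params[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mh <- opt$m[[nm]] / (1 - beta1^opt$t)
    vh <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, opt = opt)
}

## ---- training loop -------------------------------------------------------

.default_sampler <- function(train_set, arch) {
  function(idx) {
    x <- train_set$x[, , , idx, drop = FALSE]
    y <- switch(arch$kind,
                classifier_cnn = train_set$y[idx],
                bbox_cnn = train_set$y[, idx, drop = FALSE],
                unet_seg = train_set$y[, , , idx, drop = FALSE],
                unet_action = train_set$y[, , idx, drop = FALSE])
    list(x = x, y = y)
  }
}

.eval_loss <- function(model, val_set, arch, loss_fn, chunk = 16) {
  n <- dim(val_set$x)[4]
  tot <- 0
  sampler <- .default_sampler(val_set, arch)
  for (s in split(seq_len(n), ceiling(seq_len(n) / chunk))) {
    b <- sampler(s)
    out <- nn_forward(model, b$x, train = FALSE)$out
    tot <- tot + loss_fn(out, b$y)$loss * length(s)
  }
  tot / n
}

#' Train a network
#'
#' Adam optimisation of the architecture-appropriate loss (cross-entropy for
#' the classifier and action maps, mean squared error for the bounding box,
#' Dice loss for segmentation), with L2 regularisation on convolution kernels
#' only and early stopping when the validation loss fails to improve for
#' `patience` iterations. Returns the best-on-validation weights.
#'
#' @param arch an [arch_spec()].
#' @param train_set list with `x` (`[H, W, C, M]` array) and `y` (labels in
#'   the loss's expected form).
#' @param val_set like `train_set`, used for early stopping.
#' @param cfg a [train_config()].
#' @param sampler optional `function(idx)` returning an augmented batch
#'   `list(x, y)`; defaults to plain indexing of `train_set`.
#' @return trained model (list with `arch`, `params`, `state`, `log`,
#'   `config`).
#' @export
train_model <- function(arch, train_set, val_set, cfg = train_config(),
                        sampler = NULL) {
  n_train <- if (!is.null(train_set$n)) train_set$n else dim(train_set$x)[4]
  if (is.null(n_train) || n_train < 1) stop("empty training set")
  if (is.null(val_set) || (is.null(val_set$x) && is.null(val_set$n)))
    stop("empty validation set")
  loss_fn <- loss_for_kind(arch$kind)
  model <- nn_init(arch, seed = cfg$seed)
  model$dropout_p <- cfg$dropout_p
  if (is.null(sampler)) sampler <- .default_sampler(train_set, arch)
  opt <- adam_init(model$params)
  set.seed(derive_seed(cfg$seed, 2))
  best <- list(loss = Inf, iter = 0, params = model$params,
               state = model$state)
  log <- list()
  for (iter in seq_len(cfg$max_iter)) {
    idx <- sample.int(n_train, min(cfg$batch_size, n_train),
                      replace = cfg$batch_size > n_train)
    b <- sampler(idx)
    fw <- nn_forward(model, b$x, train = TRUE)
    lo <- loss_fn(fw$out, b$y)
    if (!is.finite(lo$loss))
      stop("non-finite training loss at iteration ", iter)
    grads <- nn_backward(model, fw$cache, lo$dout)
    st <- adam_step(model$params, grads, opt, cfg$learning_rate,
                    cfg$l2_weight, model$decay_params)
    model$params <- st$params; opt <- st$opt
    for (nm in names(fw$cache$new_state))
      model$state[[nm]] <- fw$cache$new_state[[nm]]
    val <- NA_real_
    if (iter %% cfg$eval_every == 0 || iter == cfg$max_iter) {
      val <- .eval_loss(model, val_set, arch, loss_fn)
      if (val < best$loss - 1e-9) {
        best <- list(loss = val, iter = iter, params = model$params,
                     state = model$state)
      } else if (iter - best$iter >= cfg$patience) {
        log[[length(log) + 1]] <- data.frame(iter = iter,
                                             train_loss = lo$loss,
                                             val_loss = val)
        break
      }
    }
    log[[length(log) + 1]] <- data.frame(iter = iter, train_loss = lo$loss,
                                         val_loss = val)
  }
  model$params <- best$params
  model$state <- best$state
  model$log <- do.call(rbind, log)
  model$config <- cfg
  model$best_val <- best$loss
  model
}

#' Save / load a model checkpoint
#'
#' Single-file archive embedding the architecture spec, weights, batch-norm
#' state and training configuration.
#'
#' @param model a trained model.
#' @param path checkpoint file (.rds).
#' @return `path` invisibly; `load_model()` returns the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model[c("arch", "params", "state", "decay_params", "meta",
                  "config", "log", "best_val")], path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
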