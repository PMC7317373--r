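## Compact CPU convolutional-network engine.
##
## No deep-learning framework ships with this R stack, so the networks the
## pipeline depends on are implemented here directly: 3x3 convolutions via
## im2col + GEMM (C++ kernels in src/ops.cpp), batch normalization, 2x2
## max-pooling, fully-connected layers with dropout, and a U-Net with skip
## connections. Tensors are [H, W, C, N] arrays. Two architecture families:
##
##   classifier_cnn / bbox_cnn: four (conv 3x3 -> batch-norm -> ReLU ->
##     max-pool 2x2) blocks followed by two fully-connected layers
##     (softmax head for the classifier, linear 4-unit head for the box).
##   unet_seg / unet_action: encoder-decoder with skip connections,
##     two (conv -> BN -> ReLU) per level, nearest-neighbour upsampling,
##     1x1 output convolution (sigmoid head for segmentation, 4-way
##     softmax head for action maps).

#' Architecture specification
#'
#' Channel widths are configuration, not contract: the `published` profile uses
#' 32/64/128/256 (FC 256) on 256 x 256 inputs, the default `desk` profile
#' uses widths that train in minutes on one CPU.
#'
#' @param kind one of "classifier_cnn", "bbox_cnn", "unet_seg", "unet_action".
#' @param in_channels input channels (5 for the peak-frame window, else 1).
#' @param in_size input side length; must be divisible by 2^4 (CNNs) or
#'   2^levels (U-Nets).
#' @param conv_widths four channel widths for the CNN conv layers.
#' @param fc_width hidden width of the first fully-connected layer.
#' @param out_units output units for CNN heads (2 classifier / 4 bbox).
#' @param base_filters,levels U-Net width and depth.
#' @param out_channels U-Net output channels (1 segmentation / 4 action).
#' @return object of class `arch_spec`.
#' @export
arch_spec <- function(kind = c("classifier_cnn", "bbox_cnn", "unet_seg",
                               "unet_action"),
                      in_channels = 1, in_size = 96,
                      conv_widths = c(8, 16, 24, 32), fc_width = 64,
                      out_units = NULL, base_filters = 8, levels = 3,
                      out_channels = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("classifier_cnn", "bbox_cnn")) {
    stopifnot(length(conv_widths) == 4, in_size %% 16 == 0)
    out_units <- out_units %||% if (kind == "classifier_cnn") 2L else 4L
  } else {
    stopifnot(in_size %% 2^levels == 0)
    out_channels <- out_channels %||% if (kind == "unet_seg") 1L else 4L
  }
  structure(list(kind = kind, in_channels = in_channels, in_size = in_size,
                 conv_widths = conv_widths, fc_width = fc_width,
                 out_units = out_units, base_filters = base_filters,
                 levels = levels, out_channels = out_channels),
            class = "arch_spec")
}

.he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

## declare a conv (+ batch-norm) block's parameters
.add_conv <- function(env, name, cin, cout, k = 3, bn = TRUE) {
  env$params[[paste0(name, "_w")]] <- .he_init(cin * k * k, cout, cin * k * k)
  env$params[[paste0(name, "_b")]] <- numeric(cout)
  env$decay <- c(env$decay, paste0(name, "_w"))
  env$meta[[name]] <- list(cin = cin, cout = cout, k = k, bn = bn)
  if (bn) {
    env$params[[paste0(name, "_bng")]] <- rep(1, cout)
    env$params[[paste0(name, "_bnb")]] <- numeric(cout)
    env$state[[paste0(name, "_mean")]] <- numeric(cout)
    env$state[[paste0(name, "_var")]] <- rep(1, cout)
  }
}

#' Initialise a model for an architecture
#'
#' He-initialised weights; batch-norm scale 1 / shift 0. The set of
#' parameters subject to L2 weight decay (convolution kernels only) is
#' recorded in `model$decay_params`.
#'
#' @param arch an [arch_spec()].
#' @param seed RNG seed for the initialisation.
#' @return model object (list with `arch`, `params`, `state`,
#'   `decay_params`).
#' @export
nn_init <- function(arch, seed = 1) {
  set.seed(as.integer(seed) %% 2147483647L)
  env <- new.env()
  env$params <- list(); env$state <- list(); env$decay <- character()
  env$meta <- list()
  if (arch$kind %in% c("classifier_cnn", "bbox_cnn")) {
    cin <- arch$in_channels
    for (i in 1:4) {
      .add_conv(env, paste0("conv", i), cin, arch$conv_widths[i])
      cin <- arch$conv_widths[i]
    }
    feat <- (arch$in_size / 16)^2 * cin
    env$params$fc1_w <- .he_init(arch$fc_width, feat, feat)
    env$params$fc1_b <- numeric(arch$fc_width)
    env$params$fc2_w <- .he_init(arch$out_units, arch$fc_width, arch$fc_width)
    env$params$fc2_b <- numeric(arch$out_units)
  } else {
    f <- arch$base_filters; L <- arch$levels
    cin <- arch$in_channels
    for (l in seq_len(L)) {
      w <- f * 2^(l - 1)
      .add_conv(env, sprintf("enc%da", l), cin, w)
      .add_conv(env, sprintf("enc%db", l), w, w)
      cin <- w
    }
    wb <- f * 2^L
    .add_conv(env, "bota", cin, wb)
    .add_conv(env, "botb", wb, wb)
    up_in <- wb
    for (l in rev(seq_len(L))) {
      w <- f * 2^(l - 1)
      .add_conv(env, sprintf("dec%da", l), up_in + w, w)
      .add_conv(env, sprintf("dec%db", l), w, w)
      up_in <- w
    }
    .add_conv(env, "head", up_in, arch$out_channels, k = 1, bn = FALSE)
  }
  list(arch = arch, params = env$params, state = env$state,
       decay_params = env$decay, meta = env$meta)
}

## ---- primitive forward/backward (R side) ---------------------------------

.bn_fwd <- function(x, g, b, rmean, rvar, train, eps = 1e-5) {
  d <- dim(x)
  r <- bn_fwd_cpp(x, g, b, rmean, rvar, d[1], d[2], d[3], d[4], train, eps)
  if (train) {
    v <- 1 / r$iv^2 - eps
    new_mean <- 0.9 * rmean + 0.1 * r$mu
    new_var <- 0.9 * rvar + 0.1 * v
  } else {
    new_mean <- rmean; new_var <- rvar
  }
  list(y = r$y, cache = list(x = x, mu = r$mu, iv = r$iv, g = g, d = d),
       mean = new_mean, var = new_var)
}

.bn_bwd <- function(dy, cache) {
  d <- cache$d
  r <- bn_bwd_cpp(cache$x, dy, cache$g, cache$mu, cache$iv,
                  d[1], d[2], d[3], d[4])
  list(dx = r$dx, dg = r$dg, db = r$db)
}

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

.upsample2_bwd <- function(dy) {
  d <- dim(dy)
  o1 <- seq(1, d[1], 2); o2 <- seq(2, d[1], 2)
  e1 <- seq(1, d[2], 2); e2 <- seq(2, d[2], 2)
  dy[o1, e1, , , drop = FALSE] + dy[o2, e1, , , drop = FALSE] +
    dy[o1, e2, , , drop = FALSE] + dy[o2, e2, , , drop = FALSE]
}

## conv (+BN) + ReLU block; cache and grads live in environments
.block_fwd <- function(model, x, name, train, cache, relu = TRUE) {
  m <- model$meta[[name]]
  d <- dim(x)
  z <- conv2d_fwd(x, model$params[[paste0(name, "_w")]],
                  model$params[[paste0(name, "_b")]],
                  d[1], d[2], d[3], d[4], m$k, m$k)
  bn <- NULL
  if (m$bn) {
    bn <- .bn_fwd(z, model$params[[paste0(name, "_bng")]],
                  model$params[[paste0(name, "_bnb")]],
                  model$state[[paste0(name, "_mean")]],
                  model$state[[paste0(name, "_var")]], train)
    if (train) {
      cache$new_state[[paste0(name, "_mean")]] <- bn$mean
      cache$new_state[[paste0(name, "_var")]] <- bn$var
    }
    a <- bn$y
  } else a <- z
  y <- if (relu) pmax(a, 0) else a
  cache[[name]] <- list(x = x, bn_cache = bn$cache, act = a, relu = relu,
                        din = d)
  y
}

.block_bwd <- function(model, dy, name, cache, grads) {
  cc <- cache[[name]]
  m <- model$meta[[name]]
  if (cc$relu) dy <- dy * (cc$act > 0)
  if (m$bn) {
    bb <- .bn_bwd(dy, cc$bn_cache)
    grads[[paste0(name, "_bng")]] <- bb$dg
    grads[[paste0(name, "_bnb")]] <- bb$db
    dy <- bb$dx
  }
  d <- cc$din
  bw <- conv2d_bwd(cc$x, model$params[[paste0(name, "_w")]], dy,
                   d[1], d[2], d[3], d[4], m$k, m$k)
  grads[[paste0(name, "_w")]] <- bw$dw
  grads[[paste0(name, "_b")]] <- bw$db
  bw$dx
}

#' Forward pass of a model
#'
#' @param model from [nn_init()] or [train_model()].
#' @param x input tensor `[H, W, C, N]`.
#' @param train if TRUE, uses batch statistics and dropout and returns a
#'   cache for [nn_backward()].
#' @return list with `out` (head output: `[units, N]` for CNNs,
#'   `[H, W, C_out, N]` for U-Nets) and `cache`.
#' @export
nn_forward <- function(model, x, train = FALSE) {
  arch <- model$arch
  cache <- new.env()
  cache$new_state <- list()
  if (arch$kind %in% c("classifier_cnn", "bbox_cnn")) {
    h <- x
    for (i in 1:4) {
      h <- .block_fwd(model, h, paste0("conv", i), train, cache)
      d <- dim(h)
      mp <- maxpool2_fwd(h, d[1], d[2], d[3], d[4])
      cache[[paste0("pool", i)]] <- list(idx = mp$idx, din = d)
      h <- mp$y
    }
    d <- dim(h)
    cache$flat_dim <- d
    hf <- matrix(h, prod(d[1:3]), d[4])
    z1 <- model$params$fc1_w %*% hf + model$params$fc1_b
    a1 <- pmax(z1, 0)
    drop_mask <- NULL
    if (train && isTRUE(model$dropout_p > 0)) {
      drop_mask <- matrix(runif(length(a1)) >= model$dropout_p,
                          nrow(a1), ncol(a1)) / (1 - model$dropout_p)
      a1 <- a1 * drop_mask
    }
    out <- model$params$fc2_w %*% a1 + model$params$fc2_b
    cache$fc <- list(hf = hf, z1 = z1, a1 = a1, drop = drop_mask)
    list(out = out, cache = cache)
  } else {
    L <- arch$levels
    skips <- vector("list", L)
    h <- x
    for (l in seq_len(L)) {
      h <- .block_fwd(model, h, sprintf("enc%da", l), train, cache)
      h <- .block_fwd(model, h, sprintf("enc%db", l), train, cache)
      skips[[l]] <- h
      d <- dim(h)
      mp <- maxpool2_fwd(h, d[1], d[2], d[3], d[4])
      cache[[sprintf("pool%d", l)]] <- list(idx = mp$idx, din = d)
      h <- mp$y
    }
    h <- .block_fwd(model, h, "bota", train, cache)
    h <- .block_fwd(model, h, "botb", train, cache)
    for (l in rev(seq_len(L))) {
      u <- .upsample2(h)
      cache[[sprintf("cat%d", l)]] <- c(dim(u)[3], dim(skips[[l]])[3])
      d <- dim(u)
      h <- array(0, c(d[1], d[2], d[3] + dim(skips[[l]])[3], d[4]))
      h[, , seq_len(d[3]), ] <- u
      h[, , d[3] + seq_len(dim(skips[[l]])[3]), ] <- skips[[l]]
      h <- .block_fwd(model, h, sprintf("dec%da", l), train, cache)
      h <- .block_fwd(model, h, sprintf("dec%db", l), train, cache)
    }
    out <- .block_fwd(model, h, "head", train, cache, relu = FALSE)
    list(out = out, cache = cache)
  }
}

#' Backward pass: gradients of all parameters
#'
#' @param model the model used in [nn_forward()].
#' @param cache cache returned by the forward pass with `train = TRUE`.
#' @param dout gradient of the loss with respect to the head output.
#' @return named list of parameter gradients.
#' @export
nn_backward <- function(model, cache, dout) {
  arch <- model$arch
  grads <- new.env()
  if (arch$kind %in% c("classifier_cnn", "bbox_cnn")) {
    fc <- cache$fc
    grads$fc2_w <- dout %*% t(fc$a1)
    grads$fc2_b <- rowSums(dout)
    da1 <- t(model$params$fc2_w) %*% dout
    if (!is.null(fc$drop)) da1 <- da1 * fc$drop
    dz1 <- da1 * (fc$z1 > 0)
    grads$fc1_w <- dz1 %*% t(fc$hf)
    grads$fc1_b <- rowSums(dz1)
    dh <- t(model$params$fc1_w) %*% dz1
    d <- cache$flat_dim
    dh <- array(dh, d)
    for (i in 4:1) {
      pl <- cache[[paste0("pool", i)]]
      dh <- maxpool2_bwd(dh, pl$idx, pl$din[1], pl$din[2], pl$din[3],
                         pl$din[4])
      dh <- .block_bwd(model, dh, paste0("conv", i), cache, grads)
    }
  } else {
    L <- arch$levels
    dh <- .block_bwd(model, dout, "head", cache, grads)
    dskip <- vector("list", L)
    for (l in seq_len(L)) {
      dh <- .block_bwd(model, dh, sprintf("dec%db", l), cache, grads)
      dh <- .block_bwd(model, dh, sprintf("dec%da", l), cache, grads)
      nc <- cache[[sprintf("cat%d", l)]]
      du <- dh[, , seq_len(nc[1]), , drop = FALSE]
      dskip[[l]] <- dh[, , nc[1] + seq_len(nc[2]), , drop = FALSE]
      dh <- .upsample2_bwd(du)
    }
    dh <- .block_bwd(model, dh, "botb", cache, grads)
    dh <- .block_bwd(model, dh, "bota", cache, grads)
    for (l in rev(seq_len(L))) {
      pl <- cache[[sprintf("pool%d", l)]]
      dh <- maxpool2_bwd(dh, pl$idx, pl$din[1], pl$din[2], pl$din[3],
                         pl$din[4])
      dh <- dh + dskip[[l]]
      dh <- .block_bwd(model, dh, sprintf("enc%db", l), cache, grads)
      dh <- .block_bwd(model, dh, sprintf("enc%da", l), cache, grads)
    }
  }
  as.list(grads)
}
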