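## Shared numeric helpers: image resampling and small utilities.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Catmull-Rom interpolation weights for separable bicubic resampling
#'
#' Builds the (out x in) row-interpolation matrix mapping an input axis of
#' length `n_in` to `n_out` samples with centre-aligned pixel coordinates
#' (output pixel i samples input coordinate (i + 0.5) * n_in / n_out - 0.5)
#' and edge replication. With `n_out == n_in` the matrix is the identity.
#' @noRd
cubic_weights <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src)
  t <- src - i0
  # Keys cubic kernel, a = -0.5 (classic bicubic)
  w <- cbind(
    ((-0.5 * t + 1) * t - 0.5) * t,
    (1.5 * t - 2.5) * t * t + 1,
    ((-1.5 * t + 2) * t + 0.5) * t,
    (0.5 * t - 0.5) * t * t
  )
  A <- matrix(0, n_out, n_in)
  for (k in 1:4) {
    idx <- clamp(i0 + (k - 2L), 0, n_in - 1L) + 1L
    A[cbind(seq_len(n_out), idx)] <- A[cbind(seq_len(n_out), idx)] + w[, k]
  }
  A
}

#' Resample a 2D image with bicubic interpolation
#'
#' Separable Catmull-Rom resampling with centre-aligned coordinates and edge
#' replication; the default interpolation used to bring cropped frames to the
#' network input size.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return numeric matrix `out_h x out_w`.
#' @export
resize_bicubic <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img))
  A <- cubic_weights(out_h, nrow(img))
  B <- cubic_weights(out_w, ncol(img))
  A %*% img %*% t(B)
}

#' Resample a 2D image (or label map) with nearest-neighbour interpolation
#'
#' Used for masks and label maps, which must stay integer-valued.
#'
#' @param img numeric or integer matrix.
#' @param out_h,out_w output size in pixels.
#' @return matrix `out_h x out_w` with values drawn from `img`.
#' @export
resize_nearest <- function(img, out_h, out_w) {
  stopifnot(is.matrix(img))
  ri <- clamp(round((seq_len(out_h) - 0.5) * nrow(img) / out_h - 0.5), 0,
              nrow(img) - 1L) + 1L
  ci <- clamp(round((seq_len(out_w) - 0.5) * ncol(img) / out_w - 0.5), 0,
              ncol(img) - 1L) + 1L
  img[ri, ci, drop = FALSE]
}

#' Affine warp of an image, output-to-input mapping
#'
#' For every output pixel (r, c) (0-based) the input location is
#' `M %*% c(r, c, 1)`; values are sampled with bilinear (images) or
#' nearest-neighbour (masks) interpolation, `fill` outside the input.
#' @param img numeric matrix.
#' @param M 2x3 affine matrix (output (row, col, 1) -> input (row, col)).
#' @param order "bilinear" or "nearest".
#' @param fill value used outside the image.
#' @return warped matrix of the same size as `img`.
#' @export
warp_affine <- function(img, M, order = c("bilinear", "nearest"), fill = 0) {
  order <- match.arg(order)
  H <- nrow(img); W <- ncol(img)
  rc <- expand.grid(r = 0:(H - 1L), c = 0:(W - 1L))
  src_r <- M[1, 1] * rc$r + M[1, 2] * rc$c + M[1, 3]
  src_c <- M[2, 1] * rc$r + M[2, 2] * rc$c + M[2, 3]
  out <- rep(fill, H * W)
  if (order == "nearest") {
    rr <- round(src_r); cc <- round(src_c)
    ok <- rr >= 0 & rr <= H - 1L & cc >= 0 & cc <= W - 1L
    out[ok] <- img[cbind(rr[ok] + 1L, cc[ok] + 1L)]
  } else {
    r0 <- floor(src_r); c0 <- floor(src_c)
    fr <- src_r - r0; fc <- src_c - c0
    ok <- r0 >= -1 & r0 <= H - 1L & c0 >= -1 & c0 <= W - 1L
    gv <- function(rr, cc) {
      v <- rep(fill, length(rr))
      ins <- rr >= 0 & rr <= H - 1L & cc >= 0 & cc <= W - 1L
      v[ins] <- img[cbind(rr[ins] + 1L, cc[ins] + 1L)]
      v
    }
    out[ok] <- ((gv(r0, c0) * (1 - fr) + gv(r0 + 1L, c0) * fr) * (1 - fc) +
                (gv(r0, c0 + 1L) * (1 - fr) + gv(r0 + 1L, c0 + 1L) * fr) * fc)[ok]
  }
  matrix(out, H, W)
}

## deterministic per-task seed derived from a base seed (kept below 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 2017L + as.integer(k) * 7919L
}
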