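## LV bounding-box detection: label rule (tight box + 20-voxel margin),
## 75 x 75 centre proposal, delta parametrisation (centre displacement +
## width/height scaling) and cropping to the 96 x 96 segmentation grid.
##
## Boxes use continuous (sub-pixel) centres and are rasterized only at crop
## time as half-open [row_min, row_max) x [col_min, col_max) pixel ranges.

#' Construct a bounding box
#'
#' @param center continuous 0-based (row, col) centre.
#' @param height,width box size in pixels (> 0).
#' @return object of class `bounding_box`.
#' @export
bounding_box <- function(center, height, width) {
  stopifnot(length(center) == 2, height > 0, width > 0)
  structure(list(center = as.double(center), height = as.double(height),
                 width = as.double(width)), class = "bounding_box")
}

#' @export
print.bounding_box <- function(x, ...) {
  cat(sprintf("<bounding_box> center (%.2f, %.2f), %g x %g (h x w)\n",
              x$center[1], x$center[2], x$height, x$width))
  invisible(x)
}

#' Construct a box delta (centre displacement + size scaling)
#'
#' @param dx,dy centre displacement in pixels; `dx` moves the column, `dy`
#'   the row coordinate.
#' @param sw,sh width and height scale factors (> 0).
#' @return object of class `box_delta`.
#' @export
box_delta <- function(dx = 0, dy = 0, sw = 1, sh = 1) {
  if (sw <= 0 || sh <= 0) stop("scale factors must be positive")
  structure(list(dx = dx, dy = dy, sw = sw, sh = sh), class = "box_delta")
}

#' Bounding-box training label from a myocardial mask
#'
#' The smallest axis-aligned box containing every mask pixel, expanded by
#' `margin` voxels on each side; rasterized corners are clipped to the image
#' bounds after expansion.
#'
#' @param mask non-empty binary matrix.
#' @param margin expansion in pixels on every side.
#' @return a [bounding_box()].
#' @export
label_bbox_from_mask <- function(mask, margin = 20) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box")
  r0 <- min(idx[, 1]) - 1 - margin; r1 <- max(idx[, 1]) - 1 + margin
  c0 <- min(idx[, 2]) - 1 - margin; c1 <- max(idx[, 2]) - 1 + margin
  r0 <- max(r0, 0); c0 <- max(c0, 0)
  r1 <- min(r1, nrow(mask) - 1); c1 <- min(c1, ncol(mask) - 1)
  bounding_box(center = c((r0 + r1) / 2, (c0 + c1) / 2),
               height = r1 - r0 + 1, width = c1 - c0 + 1)
}

#' Centre region proposal
#'
#' The fixed 75 x 75 proposal centred on the image centre, refined by the
#' detection network's delta.
#'
#' @param image_height,image_width image size in pixels (>= `size`).
#' @param size proposal side length.
#' @return a [bounding_box()].
#' @export
propose_roi <- function(image_height, image_width, size = 75) {
  if (image_height < size || image_width < size)
    stop("image smaller than the ", size, " x ", size, " proposal")
  bounding_box(center = c((image_height - 1) / 2, (image_width - 1) / 2),
               height = size, width = size)
}

#' Apply a delta transform to a proposal box
#'
#' `center' = center + (dy, dx)`, `height' = sh * height`,
#' `width' = sw * width`.
#'
#' @param proposal a [bounding_box()].
#' @param delta a [box_delta()].
#' @return the transformed [bounding_box()].
#' @export
apply_delta <- function(proposal, delta) {
  bounding_box(center = proposal$center + c(delta$dy, delta$dx),
               height = delta$sh * proposal$height,
               width = delta$sw * proposal$width)
}

#' Delta transform mapping a proposal onto a target box
#'
#' Exact inverse of [apply_delta()]: applying the returned delta to
#' `proposal` reproduces `target`.
#'
#' @param proposal,target [bounding_box()]es.
#' @return a [box_delta()].
#' @export
invert_delta <- function(proposal, target) {
  box_delta(dx = target$center[2] - proposal$center[2],
            dy = target$center[1] - proposal$center[1],
            sw = target$width / proposal$width,
            sh = target$height / proposal$height)
}

#' Rasterize a box to integer half-open pixel ranges
#'
#' @param box a [bounding_box()].
#' @param image_dim (H, W); when given, ranges are clipped to the image.
#' @return list with `row` = c(row_min, row_max) and `col` likewise,
#'   half-open 0-based.
#' @export
rasterize_box <- function(box, image_dim = NULL) {
  half_up <- function(x) floor(x + 0.5)   # round() ties-to-even would shift
  r0 <- half_up(box$center[1] - box$height / 2)
  c0 <- half_up(box$center[2] - box$width / 2)
  r1 <- r0 + half_up(box$height); c1 <- c0 + half_up(box$width)
  if (!is.null(image_dim)) {
    r0 <- max(r0, 0); c0 <- max(c0, 0)
    r1 <- min(r1, image_dim[1]); c1 <- min(c1, image_dim[2])
  }
  if (r1 <= r0 || c1 <= c0) stop("degenerate box after rasterization")
  list(row = c(r0, r1), col = c(c0, c1))
}

## corner representation used in JSON outputs
box_corners <- function(box, image_dim = NULL) {
  r <- rasterize_box(box, image_dim)
  list(center = box$center, height = box$height, width = box$width,
       row_min = r$row[1], row_max = r$row[2],
       col_min = r$col[1], col_max = r$col[2])
}

#' Fill a rasterized box as a binary mask
#'
#' @param box a [bounding_box()].
#' @param image_dim (H, W).
#' @return binary matrix with the filled box.
#' @export
box_mask <- function(box, image_dim) {
  r <- rasterize_box(box, image_dim)
  m <- matrix(0L, image_dim[1], image_dim[2])
  m[(r$row[1] + 1):r$row[2], (r$col[1] + 1):r$col[2]] <- 1L
  m
}

#' Dice coefficient between two boxes (rasterized, filled)
#'
#' @param a,b [bounding_box()]es.
#' @param image_dim (H, W) raster grid.
#' @return DSC in [0, 1].
#' @export
box_dsc <- function(a, b, image_dim) {
  dsc(box_mask(a, image_dim), box_mask(b, image_dim))
}

#' Detect the LV bounding box on the basal peak frame
#'
#' Normalizes the frame to [0, 1], feeds it to the trained regression CNN and
#' applies the predicted delta to the 75 x 75 centre proposal. Per the
#' acquisition geometry the same box is reused for the mid and apical slices.
#'
#' @param frame numeric matrix (the basal peak LV enhancement frame,
#'   256 x 256 by contract; other sizes are resampled to the network input).
#' @param model a trained bbox model checkpoint (see [train_model()]).
#' @return a [bounding_box()] in the frame's pixel coordinates.
#' @export
detect_bbox <- function(frame, model) {
  stopifnot(model$arch$kind == "bbox_cnn")
  lo <- min(frame); hi <- max(frame)
  fr <- if (hi > lo) (frame - lo) / (hi - lo) else frame * 0
  side <- model$arch$in_size
  x <- array(resize_bicubic(fr, side, side), c(side, side, 1, 1))
  pred <- as.double(nn_forward(model, x)$out)
  proposal <- propose_roi(nrow(frame), ncol(frame))
  ## regression targets are normalized: dx, dy in units of the proposal side
  delta <- box_delta(dx = pred[1] * proposal$width,
                     dy = pred[2] * proposal$height,
                     sw = max(pred[3], 1e-3), sh = max(pred[4], 1e-3))
  apply_delta(proposal, delta)
}

#' Crop a series to a box and resample to the analysis grid
#'
#' Every frame is cropped to the rasterized box and resampled to
#' `out_size x out_size` with bicubic interpolation; the effective pixel
#' spacing is rescaled accordingly. Masks accompanying a series must be
#' cropped with [crop_mask()] (nearest-neighbour).
#'
#' @param series a [perfusion_series()].
#' @param box a [bounding_box()].
#' @param out_size output side length (96 by contract).
#' @return the cropped, resampled [perfusion_series()] with an attached
#'   `crop` attribute recording the transform.
#' @export
crop_series <- function(series, box, out_size = 96) {
  d <- dim(series$frames)
  r <- rasterize_box(box, d[1:2])
  h <- r$row[2] - r$row[1]; w <- r$col[2] - r$col[1]
  frames <- array(0, c(out_size, out_size, d[3]))
  for (t in seq_len(d[3])) {
    frames[, , t] <- resize_bicubic(
      series$frames[(r$row[1] + 1):r$row[2], (r$col[1] + 1):r$col[2], t],
      out_size, out_size)
  }
  frames[frames < 0] <- 0
  out <- perfusion_series(frames,
                          pixel_spacing = series$pixel_spacing *
                            c(h, w) / out_size,
                          frame_times = series$frame_times,
                          slice_level = series$slice_level,
                          condition = series$condition,
                          subject_id = series$subject_id)
  attr(out, "crop") <- list(row0 = r$row[1], col0 = r$col[1], h = h, w = w,
                            out_size = out_size)
  out
}

#' Crop a mask with the same transform as [crop_series()]
#'
#' @param mask binary or integer label matrix.
#' @param box a [bounding_box()].
#' @param out_size output side length.
#' @return cropped, nearest-neighbour-resampled matrix (stays integer).
#' @export
crop_mask <- function(mask, box, out_size = 96) {
  r <- rasterize_box(box, dim(mask))
  resize_nearest(mask[(r$row[1] + 1):r$row[2], (r$col[1] + 1):r$col[2],
                      drop = FALSE], out_size, out_size)
}

#' Map cropped-grid coordinates back to the original image
#'
#' Inverse of the centre-aligned resampling used by [crop_series()]:
#' `orig = crop0 + (p + 0.5) * box_px / out_size - 0.5`.
#'
#' @param p 0-based (row, col) in the cropped grid (may be fractional).
#' @param crop the `crop` attribute of a cropped series.
#' @return 0-based (row, col) in the original image.
#' @export
crop_to_original <- function(p, crop) {
  c(crop$row0 + (p[1] + 0.5) * crop$h / crop$out_size - 0.5,
    crop$col0 + (p[2] + 0.5) * crop$w / crop$out_size - 0.5)
}

#' Map original-image coordinates into the cropped grid
#'
#' @param p 0-based (row, col) in the original image.
#' @param crop the `crop` attribute of a cropped series.
#' @return 0-based (row, col) in the cropped grid.
#' @export
original_to_crop <- function(p, crop) {
  c((p[1] - crop$row0 + 0.5) * crop$out_size / crop$h - 0.5,
    (p[2] - crop$col0 + 0.5) * crop$out_size / crop$w - 0.5)
}
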