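## Stage 3: myocardial segmentation on the cropped peak frame, with
## largest-connected-component postprocessing, closed-loop quality control
## and a +/- 2-frame fallback when the peak-frame segmentation fails QC.

#' Dice similarity coefficient between two binary masks
#'
#' `2|a n b| / (|a| + |b|)`; defined as 1 when both masks are empty.
#'
#' @param a,b binary matrices of the same shape.
#' @return DSC in [0, 1].
#' @export
dsc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Keep the largest 4-connected component of a mask
#'
#' @param mask binary matrix.
#' @return binary matrix with only the largest component (empty stays empty).
#' @export
largest_component <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(m)
  lab <- cc_label(m, 4L)
  sizes <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(sizes)), nrow(m), ncol(m))
}

#' Segment the myocardium on one cropped frame
#'
#' Thresholds the network's sigmoid output at `threshold` and keeps the
#' largest 4-connected component. An all-background output returns an empty
#' mask (which QC will reject).
#'
#' @param image numeric matrix (cropped peak frame, network input size).
#' @param model a trained `unet_seg` model.
#' @param threshold probability threshold.
#' @return binary matrix.
#' @export
segment_frame <- function(image, model, threshold = 0.5) {
  stopifnot(model$arch$kind == "unet_seg")
  side <- model$arch$in_size
  if (!all(dim(image) == side)) image <- resize_bicubic(image, side, side)
  x <- array(image, c(side, side, 1, 1))
  z <- nn_forward(model, x)$out[, , 1, 1]
  prob <- 1 / (1 + exp(-z))
  largest_component(prob >= threshold)
}

#' Erode a binary mask
#'
#' `px` rounds of 4-neighbour erosion. Used before kinetic curve extraction
#' to guard myocardial voxels against partial-volume contamination from the
#' adjacent blood pools introduced by crop resampling.
#'
#' @param mask binary matrix.
#' @param px erosion rounds.
#' @return eroded binary matrix.
#' @export
erode_mask <- function(mask, px = 1) {
  m <- mask != 0
  H <- nrow(m); W <- ncol(m)
  for (i in seq_len(px)) {
    pad <- matrix(FALSE, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- m
    m <- m & pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
      pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  }
  matrix(as.integer(m), H, W)
}

#' Closed-loop quality control for a myocardial mask
#'
#' TRUE iff the mask is a single 4-connected component that encloses at
#' least one hole: flood-filling the background from the image border must
#' leave at least one background component unreached. An intact myocardial
#' ring passes; a solid disk or a broken arc fails.
#'
#' @param mask binary matrix.
#' @return logical.
#' @export
qc_closed_loop <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m == 1L)) return(FALSE)
  fg <- cc_label(m, 4L)
  if (max(fg) != 1L) return(FALSE)
  any(interior_from_mask(m) != 0)
}

#' Segment with closed-loop QC and nearby-timeframe fallback
#'
#' If the peak-frame segmentation fails the closed-loop check, the network is
#' applied to frames within two timeframes of the peak, in order of distance
#' (at equal distance the later frame is tried first: contrast persists after
#' the peak). The first mask passing QC is returned; if all five candidates
#' fail, the peak-frame mask is returned flagged as failed.
#'
#' @param cropped_series a cropped [perfusion_series()] (normalized or raw;
#'   frames are min-max normalized individually before inference).
#' @param peak 0-based peak frame index.
#' @param model a trained `unet_seg` model.
#' @param threshold probability threshold for [segment_frame()].
#' @param segment_fn optional `function(image, frame_index)` producing a mask,
#'   replacing the network (used to isolate the fallback logic).
#' @return list with `mask`, `used_frame` (0-based), `passed_qc`.
#' @export
segment_with_fallback <- function(cropped_series, peak, model,
                                  threshold = 0.5, segment_fn = NULL) {
  nt <- n_frames(cropped_series)
  stopifnot(peak >= 0, peak < nt)
  norm_frame <- function(t) {
    fr <- cropped_series$frames[, , t + 1]
    lo <- min(fr); hi <- max(fr)
    if (hi > lo) (fr - lo) / (hi - lo) else fr * 0
  }
  candidates <- as.integer(peak + c(0, 1, -1, 2, -2))
  candidates <- candidates[candidates >= 0 & candidates < nt]
  if (is.null(segment_fn))
    segment_fn <- function(image, t) segment_frame(image, model, threshold)
  peak_mask <- NULL
  for (t in candidates) {
    mask <- segment_fn(norm_frame(t), t)
    if (t == peak) peak_mask <- mask
    if (qc_closed_loop(mask))
      return(list(mask = mask, used_frame = as.integer(t), passed_qc = TRUE))
  }
  list(mask = peak_mask, used_frame = as.integer(peak), passed_qc = FALSE)
}
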