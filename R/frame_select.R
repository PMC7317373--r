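## Stage 1: detection of the timeframe of peak LV contrast enhancement.
## A classifier CNN sees each frame together with its two preceding and two
## subsequent timeframes and outputs the probability that the central frame
## is the peak; the argmax over frames is the estimate.

#' Build the 5-frame input window around a timeframe
#'
#' Frames (t-2, t-1, t, t+1, t+2) with edge replication at the series
#' boundaries; returned as an `[H, W, 5]` array whose channel c corresponds
#' to offset c - 3.
#'
#' @param series a [perfusion_series()].
#' @param t 0-based frame index.
#' @return `[H, W, 5]` array.
#' @export
make_window <- function(series, t) {
  nt <- n_frames(series)
  if (t < 0 || t >= nt) stop("frame index out of range: ", t)
  idx <- clamp(t + (-2:2), 0, nt - 1) + 1
  series$frames[, , idx, drop = FALSE]
}

#' Detect the peak LV enhancement frame
#'
#' Normalizes the series to [0, 1] (so detection is invariant to global
#' intensity scaling), applies the trained classifier to every frame's
#' 5-frame window and returns the frame with the highest positive-class
#' probability; ties break toward the earlier frame.
#'
#' @param series a [perfusion_series()].
#' @param model a trained `classifier_cnn` model.
#' @param batch frames scored per forward pass.
#' @return list with `frame` (0-based index) and `trace` (per-frame
#'   probability).
#' @export
detect_peak_frame <- function(series, model, batch = 16) {
  stopifnot(model$arch$kind == "classifier_cnn")
  ns <- normalize_series(series)
  nt <- n_frames(ns)
  side <- model$arch$in_size
  trace <- numeric(nt)
  for (s in split(0:(nt - 1), ceiling(seq_len(nt) / batch))) {
    x <- array(0, c(side, side, 5, length(s)))
    for (j in seq_along(s)) {
      w <- make_window(ns, s[j])
      for (c_ in 1:5) x[, , c_, j] <- resize_bicubic(w[, , c_], side, side)
    }
    out <- nn_forward(model, x)$out
    trace[s + 1] <- .softmax_cols(out)[2, ]
  }
  list(frame = which.max(trace) - 1L, trace = trace)
}

#' Absolute frame error
#'
#' @param predicted,true 0-based frame indices.
#' @return |predicted - true| in timeframes.
#' @export
peak_error <- function(predicted, true) abs(predicted - true)

#' Classifier-free peak baseline
#'
#' The argmax over frames of the mean signal in a central disk (radius
#' `frac` of the image side); on phantoms with a sharp bolus this agrees
#' with the ground truth and serves as a sanity reference for the trained
#' model.
#'
#' @param series a [perfusion_series()].
#' @param frac disk radius as a fraction of the image side.
#' @return 0-based frame index.
#' @export
peak_baseline <- function(series, frac = 0.12) {
  d <- dim(series$frames)
  ctr <- (d[1:2] - 1) / 2
  rows <- matrix(0:(d[1] - 1), d[1], d[2])
  cols <- matrix(0:(d[2] - 1), d[1], d[2], byrow = TRUE)
  disk <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= (frac * d[1])^2
  m <- apply(series$frames, 3, function(fr) mean(fr[disk]))
  which.max(m) - 1L
}
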