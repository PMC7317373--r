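## PerfusionSeries: one short-axis slice's 2D+t image stack with metadata.

#' Construct a perfusion image series
#'
#' Container for a single slice's dynamic contrast-enhanced image stack.
#' Frames are stored as an `[H, W, T]` array so `frames[, , t]` is one
#' timeframe; pixel coordinates are 0-based `(row, col)`.
#'
#' @param frames numeric array `[H, W, T]`, intensities >= 0.
#' @param pixel_spacing length-2 numeric, mm per pixel (row, col).
#' @param frame_times strictly increasing times in seconds, length `T`.
#' @param slice_level one of "basal", "mid", "apical".
#' @param condition one of "rest", "stress".
#' @param subject_id identifier string.
#' @return object of class `perfusion_series`.
#' @export
perfusion_series <- function(frames, pixel_spacing = c(1.2, 1.2),
                             frame_times = NULL,
                             slice_level = c("basal", "mid", "apical"),
                             condition = c("rest", "stress"),
                             subject_id = "subject") {
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (any(frames < 0)) stop("negative intensities are not allowed")
  nt <- dim(frames)[3]
  if (is.null(frame_times)) frame_times <- as.double(0:(nt - 1))
  stopifnot(length(frame_times) == nt, all(diff(frame_times) > 0))
  slice_level <- match.arg(slice_level)
  condition <- match.arg(condition)
  structure(
    list(frames = frames, pixel_spacing = as.double(rep(pixel_spacing,
                                                        length.out = 2)),
         frame_times = as.double(frame_times), slice_level = slice_level,
         condition = condition, subject_id = subject_id),
    class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<perfusion_series> %s / %s / %s: %d x %d px, %d frames, %.2g x %.2g mm\n",
              x$subject_id, x$condition, x$slice_level, d[1], d[2], d[3],
              x$pixel_spacing[1], x$pixel_spacing[2]))
  invisible(x)
}

n_frames <- function(series) dim(series$frames)[3]

#' Normalize a series to the intensity range [0, 1]
#'
#' Single affine map over the whole series (not per frame): the minimum maps
#' to 0 and the maximum to 1. A constant series maps to all zeros.
#'
#' @param series a [perfusion_series()].
#' @return the series with rescaled intensities.
#' @export
normalize_series <- function(series) {
  f <- series$frames
  lo <- min(f); hi <- max(f)
  series$frames <- if (hi > lo) (f - lo) / (hi - lo) else array(0, dim(f))
  series
}

#' Read a perfusion series from a NIfTI file
#'
#' Expects a 3D volume ordered `[H, W, T]` (time last on disk). Spacing is
#' taken from the header `pixdim`; a missing/zero spacing falls back to 1.0 mm
#' with a warning. Frame times are `(0:(T-1)) * pixdim[3]` (seconds).
#'
#' @param path NIfTI file.
#' @param slice_level,condition,subject_id metadata not carried by NIfTI.
#' @return a [perfusion_series()].
#' @export
read_series <- function(path, slice_level = "basal", condition = "rest",
                        subject_id = "subject") {
  nii <- read_nifti(path)
  d <- dim(nii$data)
  if (length(d) == 4 && d[4] > 1 && d[3] == 1) {
    nii$data <- array(nii$data, d[c(1, 2, 4)])
    nii$pixdim <- nii$pixdim[c(1, 2, 4)]
    d <- dim(nii$data)
  }
  if (length(d) != 3)
    stop("expected a 3D (H x W x T) series, got ", length(d), " dimensions")
  sp <- nii$pixdim[1:2]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    warning("missing pixel spacing in NIfTI header; defaulting to 1.0 mm")
    sp <- c(1, 1)
  }
  dt <- nii$pixdim[3]
  if (!is.finite(dt) || dt <= 0) dt <- 1
  perfusion_series(nii$data, pixel_spacing = sp,
                   frame_times = (0:(d[3] - 1)) * dt,
                   slice_level = slice_level, condition = condition,
                   subject_id = subject_id)
}

#' Write a perfusion series to a NIfTI file
#'
#' Inverse of [read_series()]: data and spacing round-trip losslessly up to
#' float32 precision (pass `datatype = "float64"` for exact round trips).
#'
#' @param series a [perfusion_series()].
#' @param path output `.nii` or `.nii.gz`.
#' @param datatype on-disk datatype.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, datatype = "float64") {
  dt <- if (n_frames(series) > 1) diff(series$frame_times[1:2]) else 1
  write_nifti(series$frames, path,
              pixdim = c(series$pixel_spacing, dt), datatype = datatype)
}
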