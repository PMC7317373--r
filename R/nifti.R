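## Minimal NIfTI-1 reader/writer.
##
## No NIfTI package is available in this R stack, so the toolkit carries its
## own single-file implementation covering the subset it emits: uncompressed
## or gzipped .nii, little-endian, datatypes uint8 / int16 / int32 / float32 /
## float64, no extensions, data at vox_offset 352. The in-memory array axis
## order equals the on-disk voxel order (first/fastest axis = image row).

.nifti_dtypes <- list(
  "2"  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8),
  "4"  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16),
  "8"  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32),
  "16" = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32),
  "64" = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64)
)

.nifti_code <- function(datatype) {
  switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
         float32 = 16L, float64 = 64L,
         stop("unsupported NIfTI datatype: ", datatype))
}

.open_conn <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write an array as a NIfTI-1 file
#'
#' @param data numeric array (2-4 dimensions).
#' @param path output path; `.nii` or `.nii.gz`.
#' @param pixdim numeric vector of grid spacings, one per dimension of
#'   `data` (mm for spatial axes, seconds for the temporal axis).
#' @param datatype one of "uint8", "int16", "int32", "float32", "float64".
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, pixdim = rep(1, length(dim(data))),
                        datatype = "float32") {
  d <- dim(data)
  stopifnot(length(d) >= 2, length(d) <= 7, length(pixdim) == length(d))
  code <- .nifti_code(datatype)
  spec <- .nifti_dtypes[[as.character(code)]]
  con <- .open_conn(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wc <- function(n) writeBin(raw(n), con)
  wi(348L, 4)                               # sizeof_hdr
  wc(10 + 18 + 4 + 2 + 1 + 1)               # data_type..dim_info
  dim8 <- c(length(d), d, rep(1L, 7 - length(d)))
  wi(dim8, 2)                               # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)                 # intent_p1..intent_code
  wi(code, 2); wi(spec$bitpix, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  pd8 <- c(1, pixdim, rep(1, 7 - length(d)))
  wf(pd8)                                   # pixdim[8]
  wf(352); wf(1); wf(0)                     # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc(1)                          # slice_end, slice_code
  writeBin(as.raw(10L), con)                # xyzt_units = mm | sec
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)      # cal_max..glmin
  wc(80 + 24)                               # descrip, aux_file
  wi(c(0L, 1L), 2)                          # qform_code, sform_code = 1
  wf(rep(0, 6))                             # quatern + qoffset
  srow <- rbind(c(pd8[2], 0, 0, 0), c(0, pd8[3], 0, 0), c(0, 0, pd8[4], 0))
  wf(as.vector(t(srow)))                    # srow_x/y/z
  wc(16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wc(4)                                     # extension flag
  if (spec$what == "integer") {
    writeBin(as.integer(round(data)), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path `.nii` or `.nii.gz` file written by [write_nifti()] or any
#'   little-endian single-file NIfTI-1 with a supported datatype.
#' @return list with `data` (array), `pixdim` (spacing per axis) and
#'   `datatype` code.
#' @export
read_nifti <- function(path) {
  con <- .open_conn(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 352)
  if (length(hdr) < 348) stop("not a NIfTI-1 file: ", path)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("unsupported NIfTI (byte order or format): ", path)
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  d <- dim8[2:(nd + 1)]
  code <- ri(70, 2)
  spec <- .nifti_dtypes[[as.character(code)]]
  if (is.null(spec)) stop("unsupported NIfTI datatype code: ", code)
  pixdim <- rf(76, 8)[2:(nd + 1)]
  vox_offset <- rf(108)
  slope <- rf(112); inter <- rf(116)
  if (vox_offset > 352) readBin(con, "raw", vox_offset - 352)
  n <- prod(d)
  data <- readBin(con, spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = "little")
  if (length(data) != n) stop("truncated NIfTI data: ", path)
  if (slope != 0 && (slope != 1 || inter != 0)) data <- data * slope + inter
  dim(data) <- d
  list(data = data, pixdim = pixdim, datatype = code)
}
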