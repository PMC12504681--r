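# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No R NIfTI package is available in the supported environment, so the
# subset of the format this pipeline needs (3-D volumes, uint8 / int16 /
# int32 / float32 / float64, scl_slope/scl_inter scaling, both
# endiannesses on read) is implemented here and cross-checked against
# nibabel in the test suite.

.nifti_dtypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  name = c("uint8", "int16", "int32", "float32", "float64"),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE)

.nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param vol 3-D numeric array.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype one of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`.
#' @param pixdim voxel sizes (length 3, mm).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "float32",
                        pixdim = c(1, 1, 1)) {
  d <- dim(vol)
  if (length(d) != 3) stop("write_nifti expects a 3-D array")
  dt <- .nifti_dtypes[.nifti_dtypes$name == datatype, ]
  if (nrow(dt) != 1) stop("unsupported datatype: ", datatype)
  con <- .nii_con(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wd <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(c(3L, d, 1L, 1L, 1L, 1L), 2)               # dim[8]
  wd(c(0, 0, 0)); wi(0L, 2)                     # intent_p1..3, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wd(c(1, pixdim, 0, 0, 0, 0))                  # pixdim[8]
  wd(352)                                       # vox_offset
  wd(1); wd(0)                                  # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 10L)), con)  # slice_end, slice_code, xyzt
  wd(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  writeBin(raw(104), con)                       # descrip, aux_file
  wi(c(0L, 1L), 2)                              # qform_code=0, sform_code=1
  wd(c(0, 0, 0, 0, 0, 0))                       # quatern, qoffset
  wd(c(pixdim[1], 0, 0, 0))                     # srow_x
  wd(c(0, pixdim[2], 0, 0))                     # srow_y
  wd(c(0, 0, pixdim[3], 0))                     # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  writeBin(raw(4), con)                         # extension flag
  if (dt$what == "integer") {
    v <- as.integer(round(vol))
    if (datatype == "uint8" && (any(v < 0) || any(v > 255)))
      stop("values out of uint8 range")
    writeBin(v, con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(vol), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads single-file NIfTI-1 (`.nii` / `.nii.gz`), applying
#' `scl_slope` / `scl_inter` when set.  Only 3-D volumes (or trailing
#' singleton dimensions) are supported.
#'
#' @param path file path.
#' @return numeric 3-D array with attribute `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- .nii_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd_i <- function(off, size, n = 1, endian)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian)
  rd_f <- function(off, n = 1, endian)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  endian <- "little"
  if (rd_i(0, 4, 1, endian) != 348L) {
    endian <- "big"
    if (rd_i(0, 4, 1, endian) != 348L) stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  dims <- rd_i(40, 2, 8, endian)
  nd <- dims[1]
  d <- dims[2:(nd + 1)]
  if (any(d[-(1:3)] > 1) || nd < 3 && prod(d) < 1)
    stop("only 3-D volumes are supported")
  d3 <- c(d, 1L, 1L)[1:3]
  code <- rd_i(70, 2, 1, endian)
  dt <- .nifti_dtypes[.nifti_dtypes$code == code, ]
  if (nrow(dt) != 1) stop("unsupported NIfTI datatype code: ", code)
  pixdim <- rd_f(76, 8, endian)[2:4]
  vox_offset <- rd_f(108, 1, endian)
  slope <- rd_f(112, 1, endian)
  inter <- rd_f(116, 1, endian)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(d3)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (!is.na(slope) && slope != 0 && !(slope == 1 && inter == 0))
    vals <- vals * slope + inter
  out <- array(vals, d3)
  attr(out, "pixdim") <- pixdim
  out
}
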