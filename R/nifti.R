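# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format the pipeline needs: 3-D/4-D images, sform
# affine (falling back to pixdim when absent), little- or big-endian input,
# datatypes uint8/int16/int32/float32/float64. No extensions are written and
# any present on read are skipped via vox_offset.

.nifti_datatypes <- list(
  "2"  = list(what = "integer", size = 1, signed = FALSE, r = "uint8"),
  "4"  = list(what = "integer", size = 2, signed = TRUE,  r = "int16"),
  "8"  = list(what = "integer", size = 4, signed = TRUE,  r = "int32"),
  "16" = list(what = "double",  size = 4, signed = TRUE,  r = "float32"),
  "64" = list(what = "double",  size = 8, signed = TRUE,  r = "float64")
)

.open_raw <- function(path) {
  # gzfile() transparently reads both plain and gzip-compressed streams
  con <- gzfile(path, "rb")
  raw <- tryCatch(readBin(con, "raw", n = file.info(path)$size * 60 + 1024),
                  finally = close(con))
  raw
}

#' Read a NIfTI-1 image
#'
#' Parses a single-file NIfTI-1 image (optionally gzip-compressed) into an
#' array plus its voxel-to-world affine. The affine is taken from the sform
#' when `sform_code > 0`, otherwise built from `pixdim` and the qoffset
#' fields (rotations are not supported in that fallback).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with elements `data` (numeric array, 3-D or 4-D), `affine`
#'   (4x4 matrix, mm), `pixdim` (per-axis voxel sizes), `tr` (the 4th pixdim,
#'   seconds by this package's convention), and `descrip`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- .open_raw(path)
  rc <- function(offset, what, n, size, endian) {
    readBin(raw[(offset + 1):length(raw)], what, n = n, size = size,
            endian = endian, signed = TRUE)
  }
  endian <- "little"
  if (rc(0, "integer", 1, 4, endian) != 348L) {
    endian <- "big"
    if (rc(0, "integer", 1, 4, endian) != 348L)
      stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(raw[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("unsupported NIfTI magic '", magic, "' in ", path)
  dim0 <- rc(40, "integer", 8, 2, endian)
  ndim <- dim0[1]
  if (ndim < 3 || ndim > 4) stop("only 3-D/4-D images supported, got ndim = ", ndim)
  dims <- dim0[2:(1 + ndim)]
  datatype <- rc(70, "integer", 1, 2, endian)
  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rc(76, "double", 8, 4, endian)
  vox_offset <- rc(108, "double", 1, 4, endian)
  scl_slope <- rc(112, "double", 1, 4, endian)
  scl_inter <- rc(116, "double", 1, 4, endian)
  descrip_raw <- raw[149:228]
  nul <- which(descrip_raw == as.raw(0))
  if (length(nul)) descrip_raw <- descrip_raw[seq_len(nul[1] - 1)]
  descrip <- rawToChar(descrip_raw)
  sform_code <- rc(254, "integer", 1, 2, endian)
  n_vox <- prod(dims)
  off <- as.integer(vox_offset)
  vals <- readBin(raw[(off + 1):length(raw)], dt$what, n = n_vox,
                  size = dt$size, endian = endian, signed = dt$signed)
  if (length(vals) < n_vox) stop("truncated NIfTI data in ", path)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  affine <- diag(4)
  if (sform_code > 0) {
    affine[1, ] <- rc(280, "double", 4, 4, endian)
    affine[2, ] <- rc(296, "double", 4, 4, endian)
    affine[3, ] <- rc(312, "double", 4, 4, endian)
  } else {
    affine[1, 1] <- pixdim[2]; affine[2, 2] <- pixdim[3]; affine[3, 3] <- pixdim[4]
    affine[1:3, 4] <- rc(268, "double", 3, 4, endian)
  }
  list(data = array(vals, dim = dims), affine = affine,
       pixdim = pixdim[2:4], tr = pixdim[5], descrip = descrip)
}

#' Write a NIfTI-1 image
#'
#' Writes a 3-D or 4-D array as a little-endian single-file NIfTI-1 image
#' with the affine stored in the sform (code 1) and qform disabled. Paths
#' ending in `.gz` are gzip-compressed.
#'
#' @param data Numeric array, 3-D or 4-D; all values must be finite.
#' @param affine 4x4 voxel-to-world matrix (mm, 0-based voxel indices).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype One of `"float32"`, `"float64"`, `"int16"`, `"int32"`,
#'   `"uint8"`.
#' @param tr Repetition time in seconds, stored in `pixdim[4]`.
#' @param descrip Free-text description (at most 79 bytes are kept).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, affine, path, datatype = "float32", tr = 0,
                        descrip = "") {
  stopifnot(is.array(data), length(dim(data)) %in% c(3L, 4L),
            is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (!all(is.finite(data))) stop("non-finite values in image data")
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  dt <- .nifti_datatypes[[as.character(code)]]
  dims <- dim(data)
  ndim <- length(dims)
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wd <- function(x, size) writeBin(as.double(x), con, size = size, endian = "little")
  wc <- function(s, width) {
    b <- charToRaw(s)
    if (length(b) > width - 1) b <- b[seq_len(width - 1)]
    writeBin(c(b, raw(width - length(b))), con)
  }
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info
  wi(c(ndim, dims, rep(1L, 7 - ndim)), 2)       # dim[8]
  wd(c(0, 0, 0), 4); wi(0L, 2)                  # intent_p1-3, intent_code
  wi(code, 2); wi(dt$size * 8L, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wd(c(1, vox, tr, 0, 0, 0), 4)                 # pixdim[8] (qfac = 1)
  wd(352, 4)                                    # vox_offset
  wd(1, 4); wd(0, 4)                            # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 10L)), con)  # slice_end, slice_code, xyzt=mm|s
  wd(c(0, 0, 0, 0), 4)                          # cal_max, cal_min, slice_dur, toffset
  wi(c(0L, 0L), 4)                              # glmax, glmin
  wc(descrip, 80)
  wc("", 24)                                    # aux_file
  wi(0L, 2); wi(1L, 2)                          # qform_code = 0, sform_code = 1
  wd(rep(0, 6), 4)                              # quatern_b/c/d, qoffset_x/y/z
  wd(affine[1, ], 4); wd(affine[2, ], 4); wd(affine[3, ], 4)
  wc("", 16)                                    # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
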