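# Minimal NIfTI-1 reader/writer. No NIfTI package ships with this
# environment, so the single-file .nii / .nii.gz dialect the pipeline needs
# is implemented directly against the NIfTI-1 header layout (348-byte
# header, vox_offset 352, magic "n+1").

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2, signed = FALSE)   # uint16
)

nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`), returning the
#' data array and the voxel-to-world affine as a [metric_volume()]. Both
#' endiannesses and the common scalar datatypes (u)int8/16/32 and
#' float32/64 are accepted; `scl_slope`/`scl_inter` scaling is applied.
#' When both qform and sform are valid the sform is preferred (and a
#' message emitted if they disagree beyond 1e-3).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param ndim required dimensionality: 3, 4, or NA to accept either.
#' @return a [metric_volume()].
#' @export
read_volume <- function(path, ndim = 3) {
  con <- nii_con(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 348)
  if (length(hdr_raw) < 348) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)

  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n = n, size = 2, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n = n, size = 4, endian = endian)
  dim_   <- rd_i16(40, 8)
  datatype <- rd_i16(70, 1)
  pixdim <- rd_f32(76, 8)
  vox_offset <- rd_f32(108, 1)
  scl_slope <- rd_f32(112, 1)
  scl_inter <- rd_f32(116, 1)
  qform_code <- rd_i16(252, 1)
  sform_code <- rd_i16(254, 1)
  quat <- rd_f32(256, 3)
  qoffset <- rd_f32(268, 3)
  srow <- rbind(rd_f32(280, 4), rd_f32(296, 4), rd_f32(312, 4))

  nd <- dim_[1]
  if (nd < 3 || nd > 4) stop("only 3-D or 4-D NIfTI supported, got ", nd, "-D")
  shape <- dim_[2:(1 + nd)]
  if (!is.na(ndim) && nd != ndim) {
    stop("expected a ", ndim, "-D volume, got ", nd, "-D: ", path)
  }

  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  nvox <- prod(shape)
  # header is 348 bytes; skip to vox_offset (extensions live in between)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) < nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      (scl_slope != 1 || scl_inter != 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(as.double(vals), dim = shape)

  affine <- nii_affine(qform_code, sform_code, srow, quat, qoffset, pixdim)
  metric_volume(data, affine)
}

nii_affine <- function(qform_code, sform_code, srow, quat, qoffset, pixdim) {
  sform <- rbind(srow, c(0, 0, 0, 1))
  qform <- NULL
  if (qform_code > 0) {
    b <- quat[1]; c_ <- quat[2]; d <- quat[3]
    a2 <- 1 - b^2 - c_^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- matrix(c(
      a^2 + b^2 - c_^2 - d^2, 2 * (b * c_ - a * d),   2 * (b * d + a * c_),
      2 * (b * c_ + a * d),   a^2 + c_^2 - b^2 - d^2, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_),   2 * (c_ * d + a * b),   a^2 + d^2 - b^2 - c_^2
    ), 3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    R <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
    qform <- rbind(cbind(R, qoffset), c(0, 0, 0, 1))
  }
  if (sform_code > 0) {
    if (!is.null(qform) && max(abs(sform - qform)) > 1e-3) {
      message("qform and sform disagree; using sform")
    }
    return(sform)
  }
  if (!is.null(qform)) return(qform)
  # fall back to pixdim scaling
  diag(c(pixdim[2:4], 1))
}

#' Write a NIfTI-1 volume
#'
#' Writes a [metric_volume()] as a single-file little-endian NIfTI-1 image.
#' Integer-valued data (e.g. ROI labels) are stored as int32, everything
#' else as float64, so [read_volume()] round-trips the array losslessly.
#' The affine is stored in the sform (`sform_code = 2`, qform disabled).
#'
#' @param volume a [metric_volume()].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "metric_volume"))
  data <- volume$data
  shape <- dim(data)
  nd <- length(shape)
  integral <- is.integer(data) ||
    (all(is.finite(data)) && all(data == round(data)) &&
     max(abs(data)) < 2^31 - 1)
  datatype <- if (integral) 8L else 64L
  bitpix <- if (integral) 32L else 64L

  dim_ <- integer(8); dim_[1] <- nd; dim_[2:(1 + nd)] <- shape
  dim_[dim_ == 0L] <- 1L
  vox <- sqrt(colSums(volume$affine[1:3, 1:3]^2))
  pixdim <- c(1, vox, rep(1, 4))[1:8]

  hdr <- raw(348)
  put <- function(off, x, size) {
    b <- writeBin(x, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put(0, 348L, 4)
  put(40, as.integer(dim_), 2)
  put(70, datatype, 2)
  put(72, bitpix, 2)
  put(76, as.double(pixdim), 4)
  put(108, 352, 4)           # vox_offset (float32)
  put(112, 1, 4)             # scl_slope
  put(116, 0, 4)             # scl_inter
  put(252, 0L, 2)            # qform_code
  put(254, 2L, 2)            # sform_code
  put(280, as.double(volume$affine[1, ]), 4)
  put(296, as.double(volume$affine[2, ]), 4)
  put(312, as.double(volume$affine[3, ]), 4)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))

  con <- nii_con(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(hdr, con)
  writeBin(raw(4), con)      # no extensions
  if (integral) {
    writeBin(as.integer(data), con, size = 4, endian = "little")
  } else {
    writeBin(as.double(data), con, size = 8, endian = "little")
  }
  invisible(path)
}
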