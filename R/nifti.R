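#' @keywords internal
#' Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O.
#'
#' Supports the subset of the format this package emits and consumes:
#' 3D images, datatypes uint8 (2), int16 (4), int32 (8), float32 (16) and
#' float64 (64), scl_slope/scl_inter honored on read, little- and big-endian
#' headers on read (always little-endian on write). Internal arrays use
#' (z, y, x) axis order; NIfTI stores x fastest, so data are permuted at the
#' boundary.
NULL

.nifti_dtypes <- list(
  `2`  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64L)
)

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D array as a NIfTI-1 file
#'
#' @param arr numeric 3D array in (z, y, x) axis order.
#' @param spacing voxel spacing in mm, (z, y, x) order.
#' @param origin world origin in mm, (z, y, x) order.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param datatype NIfTI datatype code: 4 (int16), 8 (int32), 16 (float32)
#'   or 64 (float64).
#' @return `path`, invisibly.
#' @keywords internal
write_nifti <- function(arr, spacing, origin = c(0, 0, 0), path,
                        datatype = 64L) {
  stopifnot(length(dim(arr)) == 3, length(spacing) == 3, all(spacing > 0))
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  d <- dim(arr)                      # (nz, ny, nx)
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  wB <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wF <- function(x) wB(as.numeric(x), 4L)
  wS <- function(x) wB(as.integer(x), 2L)
  wI <- function(x) wB(as.integer(x), 4L)
  pad <- function(s, n) {
    r <- charToRaw(s)
    c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r))))
  }
  wI(348L)                           # sizeof_hdr
  writeBin(raw(28L), con)            # data_type[10], db_name[18]
  wI(0L); wS(0L)                     # extents, session_error
  writeBin(charToRaw("r"), con); writeBin(raw(1L), con)  # regular, dim_info
  wS(c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L))            # dim[8] (x,y,z)
  wF(c(0, 0, 0)); wS(0L)             # intent_p1..3, intent_code
  wS(as.integer(datatype)); wS(dt$bitpix); wS(0L)  # datatype,bitpix,slice_start
  wF(c(1, spacing[3], spacing[2], spacing[1], 0, 0, 0, 0))  # pixdim
  wF(352); wF(1); wF(0)              # vox_offset, scl_slope, scl_inter
  wS(0L); writeBin(raw(1L), con); writeBin(as.raw(2L), con)  # xyzt_units = mm
  wF(c(0, 0, 0, 0)); wI(c(0L, 0L))   # cal_max/min, slice_dur, toffset, gl*
  writeBin(pad("kyphofat", 80L), con)           # descrip
  writeBin(raw(24L), con)                       # aux_file
  wS(0L); wS(1L)                     # qform_code = 0, sform_code = 1
  wF(c(0, 0, 0))                     # quatern b, c, d
  wF(c(origin[3], origin[2], origin[1]))        # qoffset x, y, z
  wF(c(spacing[3], 0, 0, origin[3]))            # srow_x
  wF(c(0, spacing[2], 0, origin[2]))            # srow_y
  wF(c(0, 0, spacing[1], origin[1]))            # srow_z
  writeBin(raw(16L), con)                       # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)   # magic
  writeBin(raw(4L), con)                        # extension flag
  v <- as.vector(aperm(arr, c(3, 2, 1)))        # x fastest
  if (dt$what == "integer") {
    writeBin(as.integer(round(v)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 file into a 3D array
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `voxels` (3D array, (z, y, x) order), `spacing` (mm,
#'   (z, y, x)), `origin` (mm, (z, y, x)).
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("malformed NIfTI file (truncated header): ", path)
  rd <- function(off, what, size, n = 1L, endian) {
    readBin(hdr[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  endian <- "little"
  if (rd(0L, "integer", 4L, endian = endian) != 348L) {
    endian <- "big"
    if (rd(0L, "integer", 4L, endian = endian) != 348L)
      stop("malformed NIfTI file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1")
    stop("unsupported NIfTI file (magic '", magic, "', need single-file 'n+1')")
  dims  <- rd(40L, "integer", 2L, n = 8L, endian = endian)
  ndim  <- dims[1]
  if (ndim < 3L || any(dims[5:8] > 1L & seq(5, 8) <= ndim + 1L))
    stop("only 3D NIfTI volumes are supported (dim = ",
         paste(dims[2:(ndim + 1L)], collapse = "x"), ")")
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  datatype <- rd(70L, "integer", 2L, endian = endian)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rd(76L, "double", 4L, n = 8L, endian = endian)
  vox_offset <- rd(108L, "double", 4L, endian = endian)
  scl_slope  <- rd(112L, "double", 4L, endian = endian)
  scl_inter  <- rd(116L, "double", 4L, endian = endian)
  qoffset <- rd(268L, "double", 4L, n = 3L, endian = endian)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- as.double(nx) * ny * nz
  v <- readBin(con, dt$what, n = n, size = dt$size,
               signed = dt$signed, endian = endian)
  if (length(v) != n) stop("malformed NIfTI file (truncated data): ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  arr <- aperm(array(v, dim = c(nx, ny, nz)), c(3, 2, 1))
  list(voxels  = arr,
       spacing = c(pixdim[4], pixdim[3], pixdim[2]),
       origin  = c(qoffset[3], qoffset[2], qoffset[1]))
}
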