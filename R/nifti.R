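#' Minimal NIfTI-1 volume I/O
#'
#' Reads and writes single-file NIfTI-1 volumes (`.nii` or `.nii.gz`) carrying
#' a 3D lattice, voxel spacing and origin — the interchange format for CT,
#' dose and mask volumes in this package. Only the axis-aligned subset of the
#' format is supported: the affine is written as a diagonal sform (spacing on
#' the diagonal, origin in the translation column) and direction matrices are
#' ignored on read. Supported on-disk datatypes: uint8, int16, int32, float32,
#' float64; `scl_slope`/`scl_inter` scaling is applied on read.
#'
#' @param x A [volume_grid()] or [voi_mask()] (masks are written as uint8 0/1).
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @param datatype On-disk datatype for volumes, `"float32"` or `"float64"`.
#' @return `write_nifti()` returns `path` invisibly. `read_nifti()` returns a
#'   `volume_grid`; use [as_voi_mask()] to reinterpret a 0/1 volume as a mask.
#' @name nifti_io
NULL

.nifti_dtypes <- list(uint8 = c(code = 2, bitpix = 8),
                      int16 = c(code = 4, bitpix = 16),
                      int32 = c(code = 8, bitpix = 32),
                      float32 = c(code = 16, bitpix = 32),
                      float64 = c(code = 64, bitpix = 64))

.nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' @rdname nifti_io
#' @export
write_nifti <- function(x, path, datatype = "float32") {
  if (inherits(x, "voi_mask")) {
    x <- volume_grid(array(as.double(x$indicator), dim(x$indicator)))
    datatype <- "uint8"
  }
  stopifnot(inherits(x, "volume_grid"))
  dt <- .nifti_dtypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  con <- .nifti_open(path, "wb")
  on.exit(close(con))
  w <- function(val, size) writeBin(as.integer(val), con, size = size, endian = "little")
  wchar <- function(s, n) {
    r <- raw(n)
    b <- charToRaw(s)
    r[seq_along(b)] <- b
    writeBin(r, con)
  }
  d <- dim(x$values)
  w(348L, 4L)                               # sizeof_hdr
  writeBin(raw(35), con)                    # data_type, db_name, extents, session_error, regular
  writeBin(as.raw(0L), con)                 # dim_info
  w(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2L)  # dim[8]
  w(numeric(3), 4L)                         # intent_p1..p3 (float)
  w(c(0L, dt[["code"]], dt[["bitpix"]], 0L), 2L)  # intent_code, datatype, bitpix, slice_start
  writeBin(c(1, x$spacing, 1, 1, 1, 1), con, size = 4L, endian = "little")  # pixdim[8]
  writeBin(c(352, 1, 0), con, size = 4L, endian = "little")  # vox_offset, scl_slope, scl_inter
  w(0L, 2L); writeBin(raw(2), con)          # slice_end, slice_code, xyzt_units
  writeBin(numeric(4), con, size = 4L, endian = "little")  # cal_max..toffset
  w(c(0L, 0L), 4L)                          # glmax, glmin
  wchar("fistulomics", 80L)                 # descrip
  writeBin(raw(24), con)                    # aux_file
  w(c(0L, 1L), 2L)                          # qform_code, sform_code
  writeBin(c(numeric(3), x$origin), con, size = 4L, endian = "little")  # quatern, qoffset
  srow <- rbind(c(x$spacing[1], 0, 0, x$origin[1]),
                c(0, x$spacing[2], 0, x$origin[2]),
                c(0, 0, x$spacing[3], x$origin[3]))
  writeBin(as.numeric(t(srow)), con, size = 4L, endian = "little")
  wchar("", 16L)                            # intent_name
  wchar("n+1", 4L)                          # magic
  writeBin(raw(4), con)                     # no extensions
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(x$values), con, size = dt[["bitpix"]] / 8L, endian = "little")
  } else {
    writeBin(as.integer(x$values), con, size = dt[["bitpix"]] / 8L, endian = "little")
  }
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_nifti <- function(path) {
  con <- .nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = .nifti_endian)
  }
  .nifti_endian <- "little"
  if (readBin(hdr[1:4], "integer", 1L, 4L, endian = "little") != 348L) {
    if (readBin(hdr[1:4], "integer", 1L, 4L, endian = "big") == 348L)
      .nifti_endian <- "big"
    else stop("not a NIfTI-1 file: ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unsupported NIfTI magic: ", magic)
  dims <- rd(40L, "integer", 8L, 2L)
  if (dims[1] < 3L) stop("expected a 3D volume")
  d <- dims[2:4]
  if (dims[1] > 3L && any(dims[5:(dims[1] + 1L)] > 1L))
    stop("only single-frame 3D volumes are supported")
  code <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)
  sform <- rd(254L, "integer", 1L, 2L)
  qoffset <- rd(268L, "numeric", 3L, 4L)
  srow <- matrix(rd(280L, "numeric", 12L, 4L), 3L, 4L, byrow = TRUE)
  origin <- if (sform > 0L) srow[, 4L] else qoffset
  nvox <- prod(d)
  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- switch(as.character(code),
    "2"  = as.numeric(readBin(con, "integer", nvox, 1L, signed = FALSE, endian = .nifti_endian)),
    "4"  = as.numeric(readBin(con, "integer", nvox, 2L, endian = .nifti_endian)),
    "8"  = as.numeric(readBin(con, "integer", nvox, 4L, endian = .nifti_endian)),
    "16" = readBin(con, "numeric", nvox, 4L, endian = .nifti_endian),
    "64" = readBin(con, "numeric", nvox, 8L, endian = .nifti_endian),
    stop("unsupported NIfTI datatype code: ", code))
  if (length(vals) < nvox) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  volume_grid(array(vals, d), spacing = abs(pixdim[2:4]), origin = origin)
}

#' @rdname nifti_io
#' @param name VOI label for the reinterpreted mask.
#' @export
as_voi_mask <- function(x, name = c("ESO", "GTV", "EG")) {
  stopifnot(inherits(x, "volume_grid"))
  voi_mask(array(x$values != 0, dim(x$values)), match.arg(name))
}
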