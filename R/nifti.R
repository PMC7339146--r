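# Minimal uncompressed NIfTI-1 (.nii) reader/writer.
#
# No NIfTI package is assumed; only the header fields the pipeline needs are
# handled: dims, datatype, pixdim (voxel spacing + TR), a diagonal sform and
# the descrip field (used for provenance). Data are stored little-endian;
# the reader also accepts big-endian files. Supported datatypes: uint8 (2),
# int16 (4), int32 (8), float32 (16), float64 (64).

.nifti_dt <- function(code) {
  switch(as.character(code),
         "2"  = list(what = "integer", size = 1, signed = FALSE, bitpix = 8),
         "4"  = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16),
         "8"  = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32),
         "16" = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32),
         "64" = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64),
         stop(sprintf("unsupported NIfTI datatype code %s", code)))
}

.pad_raw <- function(s, n) {
  r <- charToRaw(substr(s, 1, n))
  c(r, raw(n - length(r)))
}

#' Write a 3D or 4D array as an uncompressed NIfTI-1 volume
#'
#' @param data A numeric/integer 3D or 4D array.
#' @param path Output path (`.nii`).
#' @param spacing Voxel spacing in mm (length 3).
#' @param tr Time step in seconds for 4D data (stored in `pixdim[4]`).
#' @param datatype NIfTI datatype code: 2 (uint8), 4 (int16), 8 (int32),
#'   16 (float32) or 64 (float64). By default integer-valued data in range
#'   are written as int32 and everything else as float64, which round-trips
#'   doubles bit-exactly.
#' @param descrip Up to 79 bytes of free text (used for provenance).
#' @return The path, invisibly.
#' @export
write_nifti <- function(data, path, spacing = c(1, 1, 1), tr = 0,
                        datatype = NULL, descrip = "") {
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stop("write_nifti() expects a 3D or 4D array")
  if (is.null(datatype)) {
    isint <- is.integer(data) ||
      (all(is.finite(data)) && all(data == round(data)) &&
         all(abs(data) < 2^31))
    datatype <- if (isint) 8L else 64L
  }
  dt <- .nifti_dt(datatype)
  dims <- integer(8)
  dims[1] <- nd
  dims[2:(1 + nd)] <- dim(data)
  dims[dims == 0L] <- 1L
  pixdim <- numeric(8)
  pixdim[1] <- 1
  pixdim[2:4] <- spacing
  pixdim[5] <- tr
  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wF <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wI(348L, 4)                       # sizeof_hdr
  writeBin(raw(10 + 18), con)       # data_type, db_name
  wI(0L, 4); wI(0L, 2)              # extents, session_error
  writeBin(c(charToRaw("r"), raw(1)), con)  # regular, dim_info
  wI(dims, 2)
  wF(c(0, 0, 0)); wI(0L, 2)         # intent_p1..3, intent_code
  wI(datatype, 2); wI(dt$bitpix, 2); wI(0L, 2)   # datatype, bitpix, slice_start
  wF(pixdim)
  wF(352)                           # vox_offset
  wF(1); wF(0)                      # scl_slope, scl_inter
  wI(0L, 2); writeBin(raw(1), con)  # slice_end, slice_code
  writeBin(as.raw(10L), con)        # xyzt_units: mm | sec
  wF(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wI(c(0L, 0L), 4)                  # glmax, glmin
  writeBin(.pad_raw(descrip, 80), con)
  writeBin(raw(24), con)            # aux_file
  wI(0L, 2); wI(1L, 2)              # qform_code, sform_code
  wF(numeric(6))                    # quatern b/c/d, qoffset x/y/z
  wF(c(spacing[1], 0, 0, 0))        # srow_x
  wF(c(0, spacing[2], 0, 0))        # srow_y
  wF(c(0, 0, spacing[3], 0))        # srow_z
  writeBin(raw(16), con)            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)             # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(round(vals)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read an uncompressed NIfTI-1 volume
#'
#' @param path Path to a `.nii` file.
#' @return A list with `data` (3D or 4D array), `spacing` (mm), `tr`
#'   (seconds), `datatype` and `descrip`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop(sprintf("%s: truncated NIfTI header", path))
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4, endian = endian)
    if (sz != 348L) stop(sprintf("%s is not a NIfTI-1 file", path))
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop(sprintf("%s: bad NIfTI magic '%s'", path, magic))
  rd <- function(off, n, size, what = "integer") {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian)
  }
  dims <- rd(40, 8, 2)
  nd <- dims[1]
  if (!nd %in% 1:7) stop(sprintf("%s: bad dim count %d", path, nd))
  datatype <- rd(70, 1, 2)
  dt <- .nifti_dt(datatype)
  pixdim <- rd(76, 8, 4, "double")
  vox_offset <- rd(108, 1, 4, "double")
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  scl_slope <- rd(112, 1, 4, "double")
  scl_inter <- rd(116, 1, 4, "double")
  shape <- pmax(dims[2:(1 + max(nd, 3))], 1L)
  n_vals <- prod(shape)
  seek(con, where = vox_offset, origin = "start")
  vals <- readBin(con, dt$what, n = n_vals, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n_vals) stop(sprintf("%s: truncated data section", path))
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape),
       spacing = pixdim[2:4], tr = pixdim[5],
       datatype = datatype, descrip = descrip)
}
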