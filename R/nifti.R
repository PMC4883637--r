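# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
# No NIfTI package ships with the target environment, so the 348-byte
# header is handled directly. Covers what this package needs: 3D/4D
# volumes, little- or big-endian files, datatypes uint8/int16/int32/
# float32/float64/uint16, and scl_slope/scl_inter rescaling on read.

.nifti_dtypes <- data.frame(
  name   = c("uint8", "int16", "int32", "float32", "float64", "uint16"),
  code   = c(2L, 4L, 8L, 16L, 64L, 512L),
  bitpix = c(8L, 16L, 32L, 32L, 64L, 16L),
  stringsAsFactors = FALSE
)

.nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3D or 4D array as a NIfTI-1 volume
#'
#' Writes a single-file little-endian NIfTI-1 image (`.nii`, or gzipped if
#' the path ends in `.gz`). `scl_slope`/`scl_inter` are written as 1/0:
#' stored values are physical values.
#'
#' @param img 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm for the three spatial axes.
#' @param datatype One of `"uint8"`, `"int16"`, `"int32"`, `"float32"`,
#'   `"float64"`, `"uint16"`. Default `"float64"` for lossless round trips.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, spacing = c(1, 1, 1), datatype = "float64") {
  nd <- length(dim(img))
  if (is.null(dim(img)) || !(nd %in% c(3L, 4L)))
    stop("img must be a 3D or 4D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  dt <- .nifti_dtypes[.nifti_dtypes$name == datatype, ]
  if (nrow(dt) != 1L) stop("unsupported datatype: ", datatype)

  d <- dim(img)
  dim8 <- rep(1L, 8L); dim8[1L] <- nd; dim8[1L + seq_len(nd)] <- as.integer(d)
  pixdim8 <- c(1, spacing, rep(1, 4))

  con <- .nifti_con(path, "wb")
  on.exit(close(con))
  en <- "little"
  w_i4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = en)
  w_i2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = en)
  w_f4 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = en)
  w_raw <- function(n) writeBin(raw(n), con)

  w_i4(348L)                      # sizeof_hdr
  w_raw(10L); w_raw(18L)          # data_type, db_name (unused)
  w_i4(0L); w_i2(0L)              # extents, session_error
  writeBin(charToRaw("r"), con)   # regular
  w_raw(1L)                       # dim_info
  w_i2(dim8)                      # dim[8]
  w_f4(c(0, 0, 0)); w_i2(0L)      # intent_p1-3, intent_code
  w_i2(dt$code); w_i2(dt$bitpix); w_i2(0L)  # datatype, bitpix, slice_start
  w_f4(pixdim8)                   # pixdim[8]
  w_f4(352); w_f4(1); w_f4(0)     # vox_offset, scl_slope, scl_inter
  w_i2(0L); w_raw(1L)             # slice_end, slice_code
  writeBin(as.raw(10L), con)      # xyzt_units = mm | sec
  w_f4(c(0, 0, 0, 0))             # cal_max, cal_min, slice_duration, toffset
  w_i4(c(0L, 0L))                 # glmax, glmin
  desc <- charToRaw("fsvpet"); w <- raw(80L); w[seq_along(desc)] <- desc
  writeBin(w, con)                # descrip
  w_raw(24L)                      # aux_file
  w_i2(0L); w_i2(1L)              # qform_code, sform_code
  w_f4(rep(0, 6))                 # quatern_b/c/d, qoffset_x/y/z
  w_f4(c(spacing[1], 0, 0, 0))    # srow_x
  w_f4(c(0, spacing[2], 0, 0))    # srow_y
  w_f4(c(0, 0, spacing[3], 0))    # srow_z
  w_raw(16L)                      # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                       # extension flag

  v <- as.vector(img)
  if (dt$name %in% c("float32", "float64")) {
    writeBin(as.numeric(v), con, size = dt$bitpix %/% 8L, endian = en)
  } else {
    iv <- as.integer(round(v))
    if (dt$name == "uint8") {
      if (any(iv < 0L | iv > 255L)) stop("values out of range for uint8")
      writeBin(as.raw(iv), con)
    } else if (dt$name == "uint16") {
      if (any(iv < 0L | iv > 65535L)) stop("values out of range for uint16")
      iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # two's complement
      writeBin(iv, con, size = 2L, endian = en)
    } else {
      writeBin(iv, con, size = dt$bitpix %/% 8L, endian = en)
    }
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzipped), applying
#' `scl_slope`/`scl_inter` rescaling when present. Both endiannesses are
#' handled.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (numeric array), `spacing` (mm, length 3) and
#'   `datatype` (storage type name).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- .nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348L)
  if (length(hdr) < 348L) stop("file too short to be NIfTI-1: ", path)
  sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "little")
  en <- "little"
  if (sz != 348L) {
    sz <- readBin(hdr[1:4], "integer", 1L, 4L, endian = "big")
    if (sz != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
    en <- "big"
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("bad NIfTI magic string in ", path)
  if (magic == "ni1") stop("two-file (.hdr/.img) NIfTI is not supported")
  rd <- function(idx, what, n, size, signed = TRUE)
    readBin(hdr[idx], what, n, size, signed = signed, endian = en)
  dim8 <- rd(41:56, "integer", 8L, 2L)
  nd <- dim8[1L]
  if (!(nd %in% c(3L, 4L))) stop("only 3D/4D NIfTI volumes are supported (dim[0]=", nd, ")")
  d <- dim8[1L + seq_len(nd)]
  dtcode <- rd(71:72, "integer", 1L, 2L)
  dt <- .nifti_dtypes[.nifti_dtypes$code == dtcode, ]
  if (nrow(dt) != 1L) stop("unsupported NIfTI datatype code: ", dtcode)
  pixdim <- rd(77:108, "numeric", 8L, 4L)
  vox_offset <- rd(109:112, "numeric", 1L, 4L)
  scl_slope <- rd(113:116, "numeric", 1L, 4L)
  scl_inter <- rd(117:120, "numeric", 1L, 4L)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(d)
  bytes <- dt$bitpix %/% 8L
  v <- switch(dt$name,
    uint8   = as.numeric(readBin(con, "integer", n, 1L, signed = FALSE, endian = en)),
    uint16  = as.numeric(readBin(con, "integer", n, 2L, signed = FALSE, endian = en)),
    int16   = as.numeric(readBin(con, "integer", n, 2L, signed = TRUE, endian = en)),
    int32   = as.numeric(readBin(con, "integer", n, 4L, signed = TRUE, endian = en)),
    float32 = readBin(con, "numeric", n, 4L, endian = en),
    float64 = readBin(con, "numeric", n, 8L, endian = en))
  if (length(v) != n) stop("truncated NIfTI data section in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  list(data = array(v, dim = d), spacing = pixdim[2:4], datatype = dt$name)
}
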