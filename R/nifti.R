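# Minimal NIfTI-1 single-file (.nii) input/output in base R.
#
# No NIfTI package is assumed at run time, so the 348-byte NIfTI-1 header
# is read and written directly.  Coverage is deliberately narrow: 2D/3D
# volumes, little-endian by default (big-endian files are byte-swapped on
# read), datatypes uint8 / int16 / int32 / float32 / float64, magic "n+1",
# slope/intercept scaling honoured on read.  That is sufficient for the
# image series, masks and parametric maps this package exchanges.

nifti_datatypes <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, bitpix = 8L),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  bitpix = 16L),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  bitpix = 32L),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  bitpix = 32L),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  bitpix = 64L))

#' Write a volume to a NIfTI-1 file
#'
#' @param data Numeric matrix (2D) or 3D array.
#' @param path Output path (`.nii`).
#' @param pixdim Voxel dimensions (mm, per data dimension); recycled/padded
#'   as needed.
#' @param datatype NIfTI datatype code: 64 (float64, default), 16
#'   (float32), 8 (int32), 4 (int16), or 2 (uint8).
#' @param descrip Description string (<= 79 chars) stored in the header.
#'
#' @return Invisibly, `path`.
#' @export
write_nifti <- function(data, path, pixdim = c(1.5, 1.5, 1),
                        datatype = 64L, descrip = "mumri") {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  dims <- dim(data)
  pixdim <- rep_len(pixdim, 3)

  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L,
                             endian = "little")
  wc <- function(s, len) {
    raw <- charToRaw(substr(s, 1, len))
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wi(348L, 4)                          # sizeof_hdr
  wc("", 10); wc("", 18)               # data_type, db_name
  wi(0L, 4); wi(0L, 2)                 # extents, session_error
  writeBin(charToRaw("r"), con)        # regular
  writeBin(as.raw(0L), con)            # dim_info
  wi(c(3L, dims, 1L, 1L, 1L, 1L), 2)   # dim[8]
  wf(c(0, 0, 0))                       # intent_p1..p3
  wi(0L, 2)                            # intent_code
  wi(datatype, 2)                      # datatype
  wi(dt$bitpix, 2)                     # bitpix
  wi(0L, 2)                            # slice_start
  wf(c(1, pixdim, 1, 1, 1, 1))         # pixdim[8]
  wf(352)                              # vox_offset
  wf(1); wf(0)                         # scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 2L)), con)  # slice_end/code, xyzt_units=mm
  wf(0); wf(0); wf(0); wf(0)           # cal_max, cal_min, slice_dur, toffset
  wi(0L, 4); wi(0L, 4)                 # glmax, glmin
  wc(descrip, 80); wc("", 24)          # descrip, aux_file
  wi(0L, 2); wi(1L, 2)                 # qform_code, sform_code
  wf(c(0, 0, 0)); wf(c(0, 0, 0))       # quatern, qoffset
  wf(c(pixdim[1], 0, 0, 0))            # srow_x
  wf(c(0, pixdim[2], 0, 0))            # srow_y
  wf(c(0, 0, pixdim[3], 0))            # srow_z
  wc("", 16)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)   # magic
  writeBin(raw(4), con)                # extension flag

  if (dt$what == "integer")
    writeBin(as.integer(round(as.vector(data))), con, size = dt$size,
             endian = "little")
  else
    writeBin(as.double(as.vector(data)), con, size = dt$size,
             endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 file
#'
#' @param path Path to a single-file NIfTI-1 (`.nii`) volume.
#'
#' @return A list with `data` (array, up to 3D), `pixdim` (mm), and
#'   `descrip`.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 352L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  ri <- function(off, size, n = 1L, signed = TRUE)
    readBin(hdr_raw[(off + 1):(off + size * n)], "integer", n = n,
            size = size, endian = endian, signed = signed)
  rf <- function(off, n = 1L)
    readBin(hdr_raw[(off + 1):(off + 4 * n)], "double", n = n, size = 4L,
            endian = endian)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unrecognised NIfTI magic: ", magic)
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  dims <- dim8[2:(1 + max(1, ndim))]
  dims <- dims[dims > 0]
  datatype <- ri(70, 2)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  pixdim <- rf(76, 8)[2:4]
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  db <- hdr_raw[149:228]
  z <- which(db == as.raw(0))[1]
  descrip <- rawToChar(db[seq_len(if (is.na(z)) 80L else z - 1L)])

  seek(con, where = vox_offset, origin = "start")
  n_vox <- prod(dims)
  vals <- readBin(con, dt$what, n = n_vox, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) != n_vox) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims), pixdim = pixdim, descrip = descrip)
}
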