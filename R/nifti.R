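# Minimal NIfTI-1 reader/writer (.nii, .nii.gz). The pre-installed R library
# carries no NIfTI package, so the standard single-file NIfTI-1 layout
# (348-byte header, 4-byte extension flag, raw data at vox_offset 352) is
# implemented here directly; the test suite cross-validates it against the
# Python nibabel implementation shipped in the same environment. Volumes are
# used in stored index order — no orientation handling (documented
# limitation).

nifti_datatypes <- list(
  uint8   = list(code = 2L,   size = 1L, what = "integer", signed = FALSE),
  int16   = list(code = 4L,   size = 2L, what = "integer", signed = TRUE),
  int32   = list(code = 8L,   size = 4L, what = "integer", signed = TRUE),
  float32 = list(code = 16L,  size = 4L, what = "double",  signed = TRUE),
  float64 = list(code = 64L,  size = 8L, what = "double",  signed = TRUE),
  uint16  = list(code = 512L, size = 2L, what = "integer", signed = FALSE)
)

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write an array as a NIfTI-1 volume
#'
#' @param arr numeric array with up to 7 dimensions (a plain vector is
#'   written as 1D).
#' @param path output path; `.nii` or `.nii.gz`.
#' @param datatype one of `"float64"` (default), `"float32"`, `"int32"`,
#'   `"int16"`, `"uint8"`.
#' @param pixdim voxel sizes per dimension (recycled; default 1).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(arr, path, datatype = "float64", pixdim = 1) {
  dt <- nifti_datatypes[[datatype]]
  if (is.null(dt)) nf_config_error("unsupported NIfTI datatype '%s'", datatype)
  dims <- dim(arr) %||% length(arr)
  if (length(dims) > 7) nf_shape_error("NIfTI supports at most 7 dimensions")
  dim8 <- rep(1L, 8); dim8[1] <- length(dims)
  dim8[seq_along(dims) + 1] <- as.integer(dims)
  pd8 <- rep(0, 8); pd8[seq_along(dims) + 1] <- rep_len(pixdim, length(dims))
  con <- nifti_open(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wflt <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wint(348L, 4)                      # sizeof_hdr
  wraw(10 + 18)                      # data_type, db_name
  wint(0L, 4); wint(0L, 2); wraw(2)  # extents, session_error, regular+dim_info
  wint(dim8, 2)                      # dim[8]
  wflt(c(0, 0, 0)); wint(0L, 2)      # intent_p1..3, intent_code
  wint(dt$code, 2)                   # datatype
  wint(dt$size * 8L, 2)              # bitpix
  wint(0L, 2)                        # slice_start
  wflt(pd8)                          # pixdim[8]
  wflt(352)                          # vox_offset
  wflt(c(1, 0))                      # scl_slope, scl_inter
  wint(0L, 2); wraw(2)               # slice_end, slice_code+xyzt_units
  wflt(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wint(c(0L, 0L), 4)                 # glmax, glmin
  desc <- charToRaw("neurofusion minimal NIfTI-1 writer")
  writeBin(c(desc, raw(80 - length(desc))), con)
  wraw(24)                           # aux_file
  wint(c(0L, 1L), 2)                 # qform_code, sform_code
  wflt(numeric(6))                   # quatern/qoffset
  srow <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 0, 1, 0))
  wflt(as.vector(t(srow)))           # srow_x/y/z
  wraw(16)                           # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con) # magic
  wraw(4)                            # extension flag -> data at 352
  if (dt$what == "integer") {
    writeBin(as.integer(arr), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.double(arr), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Handles `.nii` and `.nii.gz`, both endiannesses and the common scalar
#' datatypes; applies `scl_slope`/`scl_inter` when meaningful.
#'
#' @param path file path.
#' @return numeric array with attributes `datatype` (name) and `pixdim`.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) nf_io_error("NIfTI file '%s' not found", path)
  con <- nifti_open(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  if (length(hdr) < 348) nf_io_error("'%s' is too short to be NIfTI-1", path)
  rint <- function(off, size, n = 1, endian = "little", signed = TRUE) {
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = signed)
  }
  rflt <- function(off, n = 1, endian = "little") {
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
            endian = endian)
  }
  endian <- "little"
  if (rint(0, 4) != 348L) {
    endian <- "big"
    if (rint(0, 4, endian = "big") != 348L)
      nf_io_error("'%s' has no valid NIfTI-1 header", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    nf_io_error("'%s' has unsupported NIfTI magic '%s'", path, magic)
  dim8 <- rint(40, 2, 8, endian)
  ndim <- dim8[1]
  dims <- dim8[1 + seq_len(ndim)]
  code <- rint(70, 2, endian = endian)
  dt_name <- names(nifti_datatypes)[vapply(nifti_datatypes, function(d)
    d$code == code, logical(1))]
  if (length(dt_name) == 0)
    nf_io_error("'%s' uses unsupported NIfTI datatype code %d", path, code)
  dt <- nifti_datatypes[[dt_name]]
  pixdim <- rflt(76, 8, endian)[1 + seq_len(ndim)]
  vox_offset <- rflt(108, 1, endian)
  slope <- rflt(112, 1, endian); inter <- rflt(116, 1, endian)
  skip <- as.integer(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  data <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(data) < n)
    nf_io_error("'%s' truncated: expected %d values, got %d", path, n,
                length(data))
  if (is.finite(slope) && slope != 0 && !(slope == 1 && inter == 0)) {
    data <- data * slope + inter
  }
  arr <- array(data, dims)
  attr(arr, "datatype") <- dt_name
  attr(arr, "pixdim") <- pixdim
  arr
}
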