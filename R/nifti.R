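# Minimal NIfTI-1 codec.
#
# The pipeline only needs single-file .nii / .nii.gz volumes with voxel
# spacing; no R NIfTI package is assumed to be available at run time, so a
# compact reader/writer for the 348-byte NIfTI-1 header is kept here.
# Supported on read: dtypes uint8 (2), int16 (4), int32 (8), float32 (16),
# float64 (64); both endiannesses; scl_slope/scl_inter rescaling. Written
# files are little-endian float32 (images) or uint8 (masks) with an
# identity-times-spacing sform.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE),
  `4`  = list(what = "integer", size = 2L, signed = TRUE),
  `8`  = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double",  size = 4L, signed = TRUE),
  `64` = list(what = "double",  size = 8L, signed = TRUE)
)

nifti_con <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write a 3D volume as NIfTI-1
#'
#' @param data 3D numeric or logical array.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param spacing Voxel spacing in mm (length 3).
#' @param datatype `"float32"` (default for numeric data) or `"uint8"`
#'   (default for logical/mask data).
#' @return `path`, invisibly.
#' @export
nifti_write <- function(data, path, spacing = c(1, 1, 1),
                        datatype = if (is.logical(data)) "uint8" else "float32") {
  stopifnot(length(dim(data)) == 3, length(spacing) == 3, all(spacing > 0))
  code <- switch(datatype, uint8 = 2L, float32 = 16L,
                 stop("unsupported datatype: ", datatype))
  bitpix <- switch(datatype, uint8 = 8L, float32 = 32L)
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  end <- "little"
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = end)
  wd <- function(x) writeBin(as.double(x), con, size = 4L, endian = end)
  pad <- function(n) writeBin(raw(n), con)

  wi(348L, 4L)                                  # sizeof_hdr
  pad(35L)                                      # data_type..regular
  pad(1L)                                       # dim_info
  wi(c(3L, dim(data), 1L, 1L, 1L, 1L), 2L)      # dim[8]
  wd(c(0, 0, 0)); wi(0L, 2L)                    # intent
  wi(code, 2L); wi(bitpix, 2L); wi(0L, 2L)      # datatype, bitpix, slice_start
  wd(c(1, spacing, 1, 1, 1, 1))                 # pixdim[8] (qfac = 1)
  wd(352)                                       # vox_offset
  wd(1); wd(0)                                  # scl_slope, scl_inter
  wi(0L, 2L); pad(2L)                           # slice_end, slice_code, xyzt
  wd(c(0, 0, 0, 0))                             # cal_max..toffset
  wi(c(0L, 0L), 4L)                             # glmax, glmin
  pad(80L); pad(24L)                            # descrip, aux_file
  wi(0L, 2L); wi(1L, 2L)                        # qform_code, sform_code
  wd(c(0, 0, 0)); wd(c(0, 0, 0))                # quatern, qoffset
  wd(c(spacing[1], 0, 0, 0))                    # srow_x
  wd(c(0, spacing[2], 0, 0))                    # srow_y
  wd(c(0, 0, spacing[3], 0))                    # srow_z
  pad(16L)                                      # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con) # magic
  pad(4L)                                       # extension flag

  if (datatype == "uint8") {
    writeBin(as.raw(as.integer(data != 0)), con)
  } else {
    writeBin(as.double(data), con, size = 4L, endian = end)
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return List with `data` (3D array) and `spacing` (mm, length 3).
#' @export
nifti_read <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header: ", path)
  rd <- function(off, what, n, size, end, signed = TRUE) {
    readBin(hdr[(off + 1L):(off + n * size)], what, n = n, size = size,
            endian = end, signed = signed)
  }
  end <- "little"
  if (rd(0L, "integer", 1L, 4L, end) != 348L) {
    end <- "big"
    if (rd(0L, "integer", 1L, 4L, end) != 348L)
      stop("not a NIfTI-1 file: ", path)
  }
  dm <- rd(40L, "integer", 8L, 2L, end)
  ndim <- dm[1]
  if (ndim < 3L) stop("expected a 3D volume: ", path)
  dims <- dm[2:4]
  if (ndim > 3L && any(dm[5:(1 + ndim)] > 1L))
    stop("expected a single 3D volume, got ", ndim, "D data: ", path)
  code <- rd(70L, "integer", 1L, 2L, end)
  dt <- NIFTI_DTYPES[[as.character(code)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", code, ": ", path)
  pixdim <- rd(76L, "double", 8L, 4L, end)
  vox_offset <- rd(108L, "double", 1L, 4L, end)
  scl_slope <- rd(112L, "double", 1L, 4L, end)
  scl_inter <- rd(116L, "double", 1L, 4L, end)

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = end,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  list(data = array(vals, dim = dims), spacing = abs(pixdim[2:4]))
}
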