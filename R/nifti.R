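# Minimal NIfTI-1 I/O. No NIfTI package is a declared dependency of this
# package, so a small reader/writer for the common cases is provided:
# single-file .nii / .nii.gz, little-endian, datatypes uint8 / int16 /
# int32 / float32 / float64, 3D or 4D, with scl_slope/scl_inter applied on
# read. Spatial units are assumed mm (xyzt_units is written accordingly).

NIFTI_DT <- list(uint8 = list(code = 2L, bitpix = 8L),
                 int16 = list(code = 4L, bitpix = 16L),
                 int32 = list(code = 8L, bitpix = 32L),
                 float32 = list(code = 16L, bitpix = 32L),
                 float64 = list(code = 64L, bitpix = 64L))

#' Write a volume image as NIfTI-1
#'
#' @param vol A [volume_image()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param datatype `"float32"` (default), `"uint8"` (masks), `"int16"`,
#'   `"int32"` or `"float64"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  stopifnot(is_volume(vol))
  dt <- NIFTI_DT[[datatype]]
  if (is.null(dt)) stop("unsupported datatype ", datatype)
  d <- dim(vol$data)
  nd <- length(d)
  dim8 <- c(nd, d, rep(1L, 7 - nd))
  pixdim8 <- c(1, vol$voxel_mm, rep(0, 4))
  if (nd == 4L && !is.null(vol$schedule))
    pixdim8[5] <- mean(vol$schedule$duration) * 60  # seconds, nominal
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x, size = 4) writeBin(as.numeric(x), con, size = size,
                                       endian = "little")
  wpad <- function(n) writeBin(raw(n), con)
  wi(348L, 4)               # @0   sizeof_hdr
  wpad(35)                  # @4   data_type[10], db_name[18], extents,
                            #      session_error, regular
  wi(0L, 1)                 # @39  dim_info
  wi(dim8, 2)               # @40  dim[8]
  wf(rep(0, 3))             # @56  intent_p1..p3
  wi(0L, 2)                 # @68  intent_code
  wi(dt$code, 2)            # @70  datatype
  wi(dt$bitpix, 2)          # @72  bitpix
  wi(0L, 2)                 # @74  slice_start
  wf(pixdim8)               # @76  pixdim[8]
  wf(352)                   # @108 vox_offset
  wf(1); wf(0)              # @112 scl_slope, scl_inter
  wi(0L, 2); wi(0L, 1)      # @120 slice_end, slice_code
  wi(10L, 1)                # @123 xyzt_units (mm | s)
  wf(c(0, 0, 0, 0))         # @124 cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)          # @140 glmax, glmin
  wpad(80 + 24)             # @148 descrip, aux_file
  wi(0L, 2); wi(1L, 2)      # @252 qform_code = 0, sform_code = 1
  wf(rep(0, 6))             # @256 quatern b,c,d + qoffset x,y,z
  wf(c(vol$voxel_mm[1], 0, 0, 0))   # @280 srow_x
  wf(c(0, vol$voxel_mm[2], 0, 0))   # @296 srow_y
  wf(c(0, 0, vol$voxel_mm[3], 0))   # @312 srow_z
  wpad(16)                  # @328 intent_name
  writeChar("n+1", con, nchars = 3, eos = NULL); wpad(1)  # @344 magic
  wpad(4)                   # @348 extension flag
  v <- as.vector(vol$data)
  if (datatype %in% c("float32", "float64")) {
    writeBin(as.numeric(v), con, size = dt$bitpix / 8L, endian = "little")
  } else {
    writeBin(as.integer(round(v)), con, size = dt$bitpix / 8L,
             endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path `.nii` or `.nii.gz` file.
#' @param schedule Optional [frame_schedule()] to attach to 4D data.
#' @return A [volume_image()].
#' @export
read_nifti <- function(path, schedule = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  ri <- function(off, size, n = 1)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1)
    readBin(hdr[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = "little")
  if (ri(0, 4) != 348L) stop("not a little-endian NIfTI-1 file: ", path)
  dim8 <- ri(40, 2, 8)
  nd <- dim8[1]
  if (!(nd %in% c(3L, 4L))) stop("only 3D/4D NIfTI supported")
  d <- dim8[2:(1 + nd)]
  dtcode <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  n <- prod(d)
  # skip to vox_offset
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  v <- switch(as.character(dtcode),
    "2" = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "4" = readBin(con, "integer", n = n, size = 2, endian = "little"),
    "8" = readBin(con, "integer", n = n, size = 4, endian = "little"),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    stop("unsupported NIfTI datatype code ", dtcode))
  if (length(v) != n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    v <- v * scl_slope + scl_inter
  volume_image(array(as.numeric(v), dim = d), voxel_mm = pixdim[2:4],
               schedule = schedule)
}
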