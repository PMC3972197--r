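# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O for integer-labeled mask
# volumes. Only the header fields the package needs are interpreted: dim,
# datatype, pixdim, vox_offset. Intensity scaling, orientation matrices and
# extensions are ignored on read (masks are label images; geometry beyond the
# voxel size is handled upstream by registration, which is out of scope).

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

#' Read a NIfTI-1 volume as an integer array
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed) and returns
#' the voxel array plus the voxel size in mm. Only 3D integer-valued volumes
#' are accepted; floating-point storage is allowed when every value is a
#' whole number (common for label images exported by painting tools).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (3D integer array) and `voxel_size`
#'   (length-3 numeric, mm).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sizeof_hdr <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (sizeof_hdr != 348L) {
    swapped <- readBin(writeBin(sizeof_hdr, raw()), "integer", 1L,
                       size = 4L, endian = "big")
    if (swapped == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (sizeof_hdr = ", sizeof_hdr, "): ", path)
  }
  readBin(con, "raw", 36L)                       # skip to offset 40
  dims <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "raw", 14L)                       # intent fields
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # bitpix
  readBin(con, "integer", 1L, size = 2L, endian = endian)  # slice_start
  pixdim <- readBin(con, "double", 8L, size = 4L, endian = endian)
  vox_offset <- readBin(con, "double", 1L, size = 4L, endian = endian)
  # consumed so far: 4+36+16+14+2+2+2+32+4 = 112 bytes
  if (!(dims[1] == 3L || (dims[1] > 3L && all(dims[5:(dims[1] + 1L)] == 1L))))
    stop("expected a 3D volume, got dim[0] = ", dims[1], ": ", path)
  nx <- dims[2]; ny <- dims[3]; nz <- dims[4]
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  readBin(con, "raw", as.integer(vox_offset) - 112L)
  n <- as.double(nx) * ny * nz
  vals <- readBin(con, dt$what, n, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (dt$what == "double") {
    if (any(abs(vals - round(vals)) > 1e-6))
      stop("volume is not integer-valued; labeled masks required: ", path)
    vals <- as.integer(round(vals))
  }
  list(data = array(vals, dim = c(nx, ny, nz)),
       voxel_size = abs(pixdim[2:4]))
}

#' Write an integer array as a NIfTI-1 volume
#'
#' Writes a 3D integer array as a single-file NIfTI-1 image (int32 storage),
#' gzip-compressed when the path ends in `.gz`.
#'
#' @param data 3D integer array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Length-3 numeric voxel size in mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(data)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  w_i8  <- function(x) writeBin(as.integer(x), con, size = 1L, endian = "little")
  w_i32(348L)                                   # sizeof_hdr
  w_i8(rep(0L, 36L))                            # data_type..dim_info
  w_i16(c(3L, dim(data), 1L, 1L, 1L, 1L))       # dim[8]
  w_i8(rep(0L, 14L))                            # intent_p1..intent_code
  w_i16(8L)                                     # datatype int32
  w_i16(32L)                                    # bitpix
  w_i16(0L)                                     # slice_start
  w_f32(c(1, voxel_size, 1, 1, 1, 1))           # pixdim[8]
  w_f32(352)                                    # vox_offset
  w_f32(c(1, 0))                                # scl_slope, scl_inter
  w_i16(0L); w_i8(c(0L, 0L))                    # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0))                             # cal_max, cal_min, slice_duration
  w_f32(0)                                      # toffset
  w_i32(c(0L, 0L))                              # glmax, glmin
  w_i8(rep(0L, 80L + 24L))                      # descrip, aux_file
  w_i16(c(0L, 0L))                              # qform_code, sform_code
  w_f32(rep(0, 6))                              # quatern b/c/d, qoffset x/y/z
  w_f32(c(voxel_size[1], 0, 0, 0,               # srow_x/y/z (plain scaling)
          0, voxel_size[2], 0, 0,
          0, 0, voxel_size[3], 0))
  w_i8(rep(0L, 16L))                            # intent_name
  writeChar("n+1", con, nchars = 3L, eos = NULL); w_i8(0L)  # magic
  w_i8(rep(0L, 4L))                             # extension flag
  w_i32(data)
  invisible(path)
}
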