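# Minimal NIfTI-1 reader/writer (single-file .nii, optionally gzipped).
# Little-endian only; sform affine; float32/float64/int16/uint8 payloads;
# scl_slope/scl_inter honoured on read. No installed R package provides
# NIfTI in this environment, hence this hand-rolled implementation.

.nifti_dtypes <- list(
  uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L, signed = FALSE),
  int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L, signed = TRUE),
  int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L, signed = TRUE),
  float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L, signed = TRUE),
  float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L, signed = TRUE)
)

#' Write a volume as NIfTI-1
#'
#' Writes a 3D or 4D array as a single-file NIfTI-1 volume (gzipped when the
#' path ends in `.gz`). The affine is stored in the sform (code 1); when no
#' affine is given, a diagonal affine from `voxel_size_mm` is used.
#'
#' @param data Numeric or logical 3D/4D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Voxel edge lengths in mm (length 3).
#' @param affine Optional 4x4 grid-to-world matrix; overrides the diagonal
#'   default.
#' @param datatype One of `"float32"` (default), `"float64"`, `"int16"`,
#'   `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, voxel_size_mm = c(1, 1, 1), affine = NULL,
                        datatype = "float32") {
  dt <- .nifti_dtypes[[datatype]]
  if (is.null(dt)) stop("unsupported datatype: ", datatype)
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  nd <- length(dim(data))
  if (nd < 3L || nd > 4L) stop("data must be a 3D or 4D array")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  } else {
    stopifnot(all(dim(affine) == c(4L, 4L)))
    voxel_size_mm <- sqrt(colSums(affine[1:3, 1:3]^2))
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)

  w_i32(348L)                               # sizeof_hdr
  w_raw(36L)                                # data_type..dim_info (unused)
  dims <- rep(1L, 8L); dims[1L] <- nd; dims[seq_len(nd) + 1L] <- dim(data)
  w_i16(dims)                               # dim[8]
  w_f32(c(0, 0, 0))                         # intent_p1..p3
  w_i16(0L)                                 # intent_code
  w_i16(dt$code)                            # datatype
  w_i16(dt$bitpix)                          # bitpix
  w_i16(0L)                                 # slice_start
  pixdim <- rep(1, 8L); pixdim[1L] <- 1
  pixdim[2:4] <- voxel_size_mm
  w_f32(pixdim)                             # pixdim[8]
  w_f32(352)                                # vox_offset
  w_f32(c(1, 0))                            # scl_slope, scl_inter
  w_i16(0L); w_raw(2L)                      # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))                      # cal_max..toffset
  w_i32(c(0L, 0L))                          # glmax, glmin
  desc <- charToRaw(sprintf("fpetkin %s", as.character(utils::packageVersion("fpetkin"))))
  w_raw_padded <- function(r, n) writeBin(c(r[seq_len(min(length(r), n))], raw(max(0L, n - length(r)))), con)
  w_raw_padded(desc, 80L)                   # descrip
  w_raw(24L)                                # aux_file
  w_i16(c(0L, 1L))                          # qform_code = 0, sform_code = 1
  w_f32(rep(0, 6))                          # quatern/qoffset
  w_f32(affine[1L, ]); w_f32(affine[2L, ]); w_f32(affine[3L, ])
  w_raw(16L)                                # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  w_raw(4L)                                 # extension flag
  if (dt$what == "integer") {
    writeBin(as.integer(round(data)), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(data), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file little-endian NIfTI-1 volume (`.nii` or `.nii.gz`).
#' Scaling (`scl_slope`/`scl_inter`) is applied; the affine is taken from
#' the sform when set, otherwise a diagonal affine from `pixdim`.
#'
#' @param path Path to the file.
#' @return A list with `data` (array), `voxel_size_mm` (length 3) and
#'   `affine` (4x4 matrix).
#' @export
read_nifti <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  r_i32 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)], "integer", n, size = 4L, endian = "little")
  r_i16 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 2L * n)], "integer", n, size = 2L, endian = "little")
  r_f32 <- function(off, n = 1L) readBin(hdr[(off + 1L):(off + 4L * n)], "double", n, size = 4L, endian = "little")
  if (r_i32(0L) != 348L)
    stop("not a little-endian NIfTI-1 file: ", path)
  magic <- rawToChar(hdr[345:347])
  if (magic != "n+1") stop("unsupported NIfTI magic '", magic, "' in ", path)
  dims <- r_i16(40L, 8L)
  nd <- dims[1L]
  if (nd < 3L || nd > 4L) stop("only 3D/4D NIfTI supported (got ", nd, "D)")
  shape <- dims[2L:(nd + 1L)]
  code <- r_i16(70L)
  dt_i <- which(vapply(.nifti_dtypes, function(d) d$code == code, logical(1)))
  if (length(dt_i) == 0L) stop("unsupported NIfTI datatype code ", code)
  dt <- .nifti_dtypes[[dt_i]]
  pixdim <- r_f32(76L, 8L)
  vox_offset <- r_f32(108L)
  scl_slope <- r_f32(112L)
  scl_inter <- r_f32(116L)
  sform_code <- r_i16(254L)
  if (sform_code > 0L) {
    affine <- rbind(r_f32(280L, 4L), r_f32(296L, 4L), r_f32(312L, 4L), c(0, 0, 0, 1))
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  } else {
    voxel_size <- pixdim[2:4]
    affine <- diag(c(voxel_size, 1))
  }
  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n = n, size = dt$size,
                  signed = dt$signed, endian = "little")
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape), voxel_size_mm = voxel_size,
       affine = affine)
}
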