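# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the deployment environment, so the small
# subset of NIfTI-1 this pipeline needs is implemented directly: single-file
# .nii / .nii.gz, datatypes uint8/int16/int32/float32/float64, 3-D or 4-D,
# sform (preferred) or qform/pixdim affines, little- or big-endian input,
# little-endian output. Scaling (scl_slope/scl_inter) is applied on read.

.nifti_dtypes <- list(
  `2`   = list(what = "integer", size = 1, signed = FALSE, bitpix = 8L),
  `4`   = list(what = "integer", size = 2, signed = TRUE,  bitpix = 16L),
  `8`   = list(what = "integer", size = 4, signed = TRUE,  bitpix = 32L),
  `16`  = list(what = "double",  size = 4, signed = TRUE,  bitpix = 32L),
  `64`  = list(what = "double",  size = 8, signed = TRUE,  bitpix = 64L),
  `256` = list(what = "integer", size = 1, signed = TRUE,  bitpix = 8L),
  `512` = list(what = "integer", size = 2, signed = FALSE, bitpix = 16L)
)

.quaternion_affine <- function(b, c, d, qx, qy, qz, pixdim) {
  a2 <- 1 - b * b - c * c - d * d
  a <- if (a2 < 0) 0 else sqrt(a2)
  qfac <- if (pixdim[1] < 0) -1 else 1
  R <- matrix(c(
    a * a + b * b - c * c - d * d, 2 * (b * c + a * d), 2 * (b * d - a * c),
    2 * (b * c - a * d), a * a + c * c - b * b - d * d, 2 * (c * d + a * b),
    2 * (b * d + a * c), 2 * (c * d - a * b), a * a + d * d - b * b - c * c
  ), 3, 3)
  S <- diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  aff <- diag(4)
  aff[1:3, 1:3] <- R %*% S
  aff[1:3, 4] <- c(qx, qy, qz)
  aff
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file
#' @return a list with `img` (numeric array), `affine` (4x4 voxel-to-world,
#'   0-based voxel indices), `voxel_size_mm`, `descrip`
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("cannot read NIfTI file: ", path)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  endian <- "little"
  szh <- readBin(con, "integer", 1, 4, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh_sw <- readBin(rev(writeBin(szh, raw())), "integer", 1, 4, endian = "little")
    if (szh_sw != 348L) stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
  }
  readBin(con, "raw", 36)                                   # unused fields + dim_info
  dim0 <- readBin(con, "integer", 8, 2, endian = endian)    # dim[0..7]
  readBin(con, "double", 3, 4, endian = endian)             # intent_p1..p3
  readBin(con, "integer", 1, 2, endian = endian)            # intent_code
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  readBin(con, "integer", 2, 2, endian = endian)            # bitpix, slice_start
  pixdim <- readBin(con, "double", 8, 4, endian = endian)
  vox_offset <- readBin(con, "double", 1, 4, endian = endian)
  scl_slope <- readBin(con, "double", 1, 4, endian = endian)
  scl_inter <- readBin(con, "double", 1, 4, endian = endian)
  readBin(con, "raw", 4)                                    # slice_end/code/xyzt_units
  readBin(con, "double", 4, 4, endian = endian)             # cal/slice_dur/toffset
  readBin(con, "integer", 2, 4, endian = endian)            # glmax/glmin
  descrip_raw <- readBin(con, "raw", 80)
  nul <- which(descrip_raw == 0)
  descrip <- rawToChar(descrip_raw[seq_len(if (length(nul)) nul[1] - 1L else 80L)])
  readBin(con, "raw", 24)                                   # aux_file
  qform_code <- readBin(con, "integer", 1, 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, 2, endian = endian)
  quat <- readBin(con, "double", 6, 4, endian = endian)
  srow <- matrix(readBin(con, "double", 12, 4, endian = endian), 3, 4, byrow = TRUE)
  readBin(con, "raw", 16)                                   # intent_name
  magic_raw <- readBin(con, "raw", 4)
  magic <- rawToChar(magic_raw[magic_raw != 0])
  if (!grepl("^n\\+1", magic)) stop("unsupported NIfTI layout (magic '", magic,
                                    "'); only single-file n+1 is supported")
  ndim <- dim0[1]
  if (ndim < 3 || ndim > 4) stop("non-3-D image (dim[0] = ", ndim,
                                 "): only 3-D/4-D volumes are supported")
  dims <- dim0[2:(1 + ndim)]
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  skip <- round(vox_offset) - 348L
  if (skip > 0) readBin(con, "raw", skip)
  n <- prod(dims)
  img <- readBin(con, dt$what, n, dt$size, signed = dt$signed, endian = endian)
  if (length(img) != n) stop("truncated NIfTI data in ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    img <- img * scl_slope + scl_inter
  img <- array(as.numeric(img), dim = dims)
  affine <- if (sform_code > 0) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0) {
    .quaternion_affine(quat[1], quat[2], quat[3], quat[4], quat[5], quat[6], pixdim)
  } else {
    diag(c(pixdim[2:4], 1))
  }
  list(img = img, affine = affine,
       voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2)),
       descrip = descrip)
}

#' Write a NIfTI-1 volume
#'
#' Writes a single-file little-endian `.nii` or `.nii.gz` with an sform
#' affine. `datatype` may be `"uint8"`, `"int16"`, `"int32"`, `"float32"`
#' or `"float64"`.
#'
#' @param img 3-D or 4-D numeric array
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices)
#' @param path output path; `.gz` suffix selects gzip compression
#' @param datatype on-disk representation
#' @param descrip free text stored in the header (max 79 bytes)
#' @export
write_nifti <- function(img, affine, path, datatype = "float32", descrip = "") {
  dims <- dim(img)
  if (is.null(dims) || !(length(dims) %in% c(3L, 4L)))
    stop("img must be a 3-D or 4-D array")
  code <- switch(datatype, uint8 = 2L, int16 = 4L, int32 = 8L,
                 float32 = 16L, float64 = 64L,
                 stop("unsupported datatype: ", datatype))
  dt <- .nifti_dtypes[[as.character(code)]]
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, 4, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, 2, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, 4, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_chr <- function(s, n) {
    r <- charToRaw(substr(s, 1, n - 1))
    writeBin(c(r, raw(n - length(r))), con)
  }
  w_i32(348L); w_raw(36)
  w_i16(c(length(dims), dims, rep(1L, 7 - length(dims))))   # dim[0..7]
  w_f32(c(0, 0, 0)); w_i16(0L)                              # intent
  w_i16(code); w_i16(dt$bitpix); w_i16(0L)
  w_f32(c(1, vox, rep(1, 8 - 4)))                           # pixdim (qfac = 1)
  w_f32(352); w_f32(1); w_f32(0)                            # vox_offset, scl
  w_raw(4); w_f32(c(0, 0, 0, 0)); w_i32(c(0L, 0L))
  w_chr(descrip, 80); w_raw(24)
  w_i16(0L); w_i16(2L)                                      # qform 0, sform 2
  w_f32(rep(0, 6))
  w_f32(t(affine[1:3, , drop = FALSE]))
  w_raw(16); w_chr("n+1", 4)
  w_raw(4)                                                  # extension flag
  vals <- as.vector(img)
  if (dt$what == "integer") vals <- as.integer(round(vals))
  writeBin(if (dt$what == "integer") vals else as.double(vals),
           con, dt$size, endian = "little")
  invisible(path)
}
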