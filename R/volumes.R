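#' Image volume and ROI containers
#'
#' An `image_volume` couples a 3D intensity array in `(z, y, x)` order
#' with its voxel spacing in mm (same order).  An `roi_set` holds the
#' tumor and bladder masks as logical arrays on the same grid.
#'
#' @param data numeric 3D array, dimensions `(nz, ny, nx)`.
#' @param spacing numeric length-3 vector of voxel spacings in mm,
#'   `(z, y, x)` order; all entries must be positive.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (z, y, x) in mm")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @rdname image_volume
#' @param tumor,bladder logical arrays matching the volume grid.
#' @export
roi_set <- function(tumor, bladder) {
  if (!identical(dim(tumor), dim(bladder)))
    stop("tumor and bladder masks must share a grid")
  structure(list(tumor = tumor != 0, bladder = bladder != 0),
            class = "roi_set")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm (z,y,x)\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

# ---- Minimal NIfTI-1 I/O -------------------------------------------------
# No NIfTI reader ships with the installed R stack, so a minimal
# single-file NIfTI-1 (.nii / .nii.gz) codec is provided.  Scope: one 3D
# scalar volume, datatypes uint8/int16/int32/float32/float64, spacing in
# pixdim with an identity-direction sform.  Data on disk follow the NIfTI
# convention (x fastest); in memory arrays are (z, y, x).

nifti_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read and write single-volume NIfTI-1 files
#'
#' `write_nifti()` stores a 3D array (or [image_volume]) with its voxel
#' spacing; `read_nifti()` returns an [image_volume].  Masks round-trip
#' exactly when written as `uint8`; float intensities are stored as
#' `float32` by default (round-trip within 1e-6 of values of order 1).
#'
#' @param x an [image_volume], or a 3D array in `(z, y, x)` order.
#' @param path output file; `.gz` suffix triggers gzip compression.
#' @param spacing voxel spacing `(z, y, x)` in mm (ignored when `x` is an
#'   [image_volume]).
#' @param datatype one of "uint8", "int16", "int32", "float32", "float64".
#' @return `read_nifti()` returns an [image_volume]; `write_nifti()`
#'   returns `path` invisibly.
#' @export
write_nifti <- function(x, path, spacing = NULL, datatype = "float32") {
  if (inherits(x, "image_volume")) {
    spacing <- x$spacing
    x <- x$data
  }
  if (is.null(spacing)) stop("`spacing` is required for a bare array")
  if (length(dim(x)) != 3L) stop("only 3D volumes are supported")
  dt <- switch(datatype,
    uint8   = list(code = 2L,  bitpix = 8L,  what = "integer", size = 1L),
    int16   = list(code = 4L,  bitpix = 16L, what = "integer", size = 2L),
    int32   = list(code = 8L,  bitpix = 32L, what = "integer", size = 4L),
    float32 = list(code = 16L, bitpix = 32L, what = "double",  size = 4L),
    float64 = list(code = 64L, bitpix = 64L, what = "double",  size = 8L),
    stop("unsupported datatype: ", datatype))
  dims <- dim(x)                       # (nz, ny, nx)
  sp_xyz <- rev(as.numeric(spacing))   # (x, y, z) for the header
  con <- nifti_con(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(348L, 4)                                   # sizeof_hdr
  writeBin(raw(36), con)                        # data_type..dim_info (10+18+4+2+1+1)
  wi(c(3L, rev(dims), 1L, 1L, 1L, 1L), 2)       # dim[8]: x,y,z fastest-first
  wf(c(0, 0, 0)); wi(0L, 2)                     # intent_p*, intent_code
  wi(dt$code, 2); wi(dt$bitpix, 2); wi(0L, 2)   # datatype, bitpix, slice_start
  wf(c(1, sp_xyz, 0, 0, 0, 0))                  # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)                         # vox_offset, scl_slope, scl_inter
  wi(0L, 2); writeBin(as.raw(c(0L, 2L)), con)   # slice_end, slice_code, xyzt=mm
  wf(c(0, 0, 0, 0)); wi(c(0L, 0L), 4)           # cal/slice_duration/toffset, glmax/glmin
  writeBin(raw(104), con)                       # descrip + aux_file
  wi(c(0L, 1L), 2)                              # qform_code = 0, sform_code = 1
  wf(c(0, 0, 0, 0, 0, 0))                       # quaternions + offsets
  wf(c(sp_xyz[1], 0, 0, 0))                     # srow_x
  wf(c(0, sp_xyz[2], 0, 0))                     # srow_y
  wf(c(0, 0, sp_xyz[3], 0))                     # srow_z
  writeBin(raw(16), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)    # magic
  writeBin(raw(4), con)                         # no extensions
  vals <- aperm(x, c(3, 2, 1))                  # -> x fastest on disk
  if (dt$what == "integer") {
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- nifti_con(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file: ", path)
  ri <- function(off, size, n = 1L)
    readBin(hdr[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little")
  rf <- function(off, n = 1L)
    readBin(hdr[(off + 1):(off + 4 * n)], "double", n = n, size = 4L,
            endian = "little")
  if (ri(0, 4) != 348L) stop("bad NIfTI header in ", path)
  dim8 <- ri(40, 2, 8)
  ndim <- dim8[1]
  if (ndim < 3L) dim8[(ndim + 2):4] <- 1L
  nxyz <- dim8[2:4]
  dtcode <- ri(70, 2)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108)
  scl_slope <- rf(112); scl_inter <- rf(116)
  dt <- switch(as.character(dtcode),
    "2"  = list(what = "integer", size = 1L, signed = FALSE),
    "4"  = list(what = "integer", size = 2L, signed = TRUE),
    "8"  = list(what = "integer", size = 4L, signed = TRUE),
    "16" = list(what = "double",  size = 4L, signed = TRUE),
    "64" = list(what = "double",  size = 8L, signed = TRUE),
    stop("unsupported NIfTI datatype code ", dtcode, " in ", path))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(nxyz)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) != n) stop("truncated NIfTI data in ", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  arr <- aperm(array(vals, dim = nxyz), c(3, 2, 1))  # -> (z, y, x)
  image_volume(arr, spacing = rev(abs(pixdim[2:4])))
}
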