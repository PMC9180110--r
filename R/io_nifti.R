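#' Minimal NIfTI-1 volume I/O
#'
#' The package reads and writes single-file NIfTI-1 volumes (`.nii`, or
#' `.nii.gz` via R's built-in gzip connections) with an axis-aligned
#' isotropic affine, which is all the pipeline requires. Data are written
#' as little-endian float32 with an sform carrying the grid affine; readers
#' accept uint8, int16, int32, float32 and float64 payloads.
#'
#' @param x a 3-D or 4-D numeric/logical array. If it carries a
#'   `voxel_grid` attribute (`attr(x, "grid")`) that grid's affine is
#'   written; otherwise `grid` must be supplied.
#' @param path output file name, ending in `.nii` or `.nii.gz`.
#' @param grid a [voxel_grid]; defaults to `attr(x, "grid")`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, grid = attr(x, "grid", exact = TRUE)) {
  if (is.null(grid)) stop("supply `grid` or attach one as attr(x, 'grid')")
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("`x` must be a 3-D or 4-D array")
  if (any(d[1:3] != grid$dims)) stop("array dims do not match grid dims")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))

  wi16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  wi32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf32 <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wch  <- function(n) writeBin(raw(n), con)

  ndim <- length(d)
  dimv <- c(ndim, d, rep(1L, 7L - ndim))
  pixdim <- c(1, rep(grid$voxel_size, 3), rep(0, 4))

  wi32(348L)                              # sizeof_hdr
  wch(36L)                                # unused: data_type..dim_info
  wi16(dimv)                              # dim[8]
  wf32(c(0, 0, 0))                        # intent_p1..p3
  wi16(0L)                                # intent_code
  wi16(16L)                               # datatype = float32
  wi16(32L)                               # bitpix
  wi16(0L)                                # slice_start
  wf32(pixdim)                            # pixdim[8]
  wf32(352)                               # vox_offset
  wf32(c(1, 0))                           # scl_slope, scl_inter
  wi16(0L); wch(1L)                       # slice_end, slice_code
  writeBin(as.raw(2L), con)               # xyzt_units = mm
  wf32(c(0, 0, 0, 0))                     # cal_max, cal_min, slice_duration, toffset
  wi32(c(0L, 0L))                         # glmax, glmin
  wch(80L); wch(24L)                      # descrip, aux_file
  wi16(0L); wi16(1L)                      # qform_code, sform_code
  wf32(rep(0, 6))                         # quaterns + qoffsets
  aff <- grid_affine(grid)
  wf32(aff[1, ]); wf32(aff[2, ]); wf32(aff[3, ])
  wch(16L)                                # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0L)), con)  # magic
  wch(4L)                                 # extension flag
  wf32(as.numeric(x))
  invisible(path)
}

#' @rdname write_nifti
#' @param ap_axis AP axis to record on the returned grid (default 2).
#' @return `read_nifti` returns the array with a `voxel_grid` attached as
#'   `attr(, "grid")`.
#' @export
read_nifti <- function(path, ap_axis = 2) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  ri16 <- function(n) readBin(con, "integer", n, size = 2L, endian = "little")
  ri32 <- function(n) readBin(con, "integer", n, size = 4L, endian = "little")
  rf32 <- function(n) readBin(con, "numeric", n, size = 4L, endian = "little")

  hdr_size <- ri32(1L)
  if (!identical(hdr_size, 348L)) stop("not a little-endian NIfTI-1 file: ", path)
  readBin(con, "raw", 36L)
  dimv <- ri16(8L)
  rf32(3L); ri16(1L)
  datatype <- ri16(1L); ri16(2L)
  pixdim <- rf32(8L)
  vox_offset <- rf32(1L)
  scl <- rf32(2L)
  ri16(1L); readBin(con, "raw", 2L)
  rf32(4L); ri32(2L)
  readBin(con, "raw", 104L)
  ri16(2L)                                # qform_code, sform_code
  rf32(6L)
  srow <- matrix(rf32(12L), nrow = 3, byrow = TRUE)
  readBin(con, "raw", 16L)
  magic <- readBin(con, "raw", 4L)
  if (!identical(rawToChar(magic[1:3]), "n+1")) stop("unsupported NIfTI magic in ", path)
  readBin(con, "raw", as.integer(vox_offset) - 348L)

  ndim <- dimv[1]
  d <- dimv[2:(1 + ndim)]
  n <- prod(d)
  x <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n, size = 2L, endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n, size = 4L, endian = "little")),
    "16" = readBin(con, "numeric", n, size = 4L, endian = "little"),
    "64" = readBin(con, "numeric", n, size = 8L, endian = "little"),
    stop("unsupported NIfTI datatype code ", datatype))
  if (length(x) != n) stop("truncated NIfTI data in ", path)
  if (scl[1] != 0 && !(scl[1] == 1 && scl[2] == 0)) x <- x * scl[1] + scl[2]
  dim(x) <- d
  vs <- pixdim[2]
  offdiag <- srow[1:3, 1:3]; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(vs, 1)))
    stop("oblique affine in ", path, ": this reader supports axis-aligned volumes only")
  if (all(abs(diag(srow[1:3, 1:3])) > 0)) vs <- abs(srow[1, 1])
  origin <- srow[, 4]
  attr(x, "grid") <- voxel_grid(d[1:3], voxel_size = vs, origin = origin,
                                ap_axis = ap_axis)
  x
}
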