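## Minimal NIfTI-1 reader/writer for ActivityVolume objects.
##
## The pre-installed R stack has no NIfTI package, so the small fixed
## 348-byte NIfTI-1 header is implemented directly: single-file .nii (or
## .nii.gz via gzip connections), little-endian, float32/float64/int16
## data with scl_slope/scl_inter support, sform spacing/origin. This is
## deliberately not a general NIfTI implementation (no extensions, no
## qform rotations, 3-D only) - enough to exchange calibrated activity
## volumes with standard tools.

niftiCon <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

padRaw <- function(s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  if (length(b) > n) b <- b[seq_len(n)]
  r[seq_along(b)] <- b
  r
}

#' Write an ActivityVolume as NIfTI-1
#'
#' Writes a single-file little-endian NIfTI-1 volume (float32), voxel
#' spacing in pixdim/sform (mm), intensities in Bq/ml, and the acquisition
#' time (hours p.i.) recorded in the \code{descrip} field as
#' \code{"tpi_h=<hours>"} so that \code{\link{readActivityVolume}}
#' round-trips it.
#'
#' @param vol an \linkS4class{ActivityVolume}.
#' @param path output path ending in .nii or .nii.gz.
#' @return \code{path}, invisibly.
#' @export
writeActivityVolume <- function(vol, path) {
  stopifnot(is(vol, "ActivityVolume"))
  d <- dim(vol@voxels)
  con <- niftiCon(path, "wb")
  on.exit(close(con))
  wInt <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  wFlt <- function(x) writeBin(as.numeric(x), con, size = 4L,
                               endian = "little")
  wInt(348L, 4)                                  # sizeof_hdr
  writeBin(raw(35), con)                         # data_type..regular
  writeBin(raw(1), con)                          # dim_info
  wInt(c(3L, d, 1L, 1L, 1L, 1L), 2)              # dim[8]
  wFlt(c(0, 0, 0)); wInt(0L, 2)                  # intent_p1..code
  wInt(16L, 2); wInt(32L, 2); wInt(0L, 2)        # datatype float32, bitpix
  wFlt(c(1, rep(vol@voxelSize, 3), 1, 1, 1, 1))  # pixdim[8]
  wFlt(352)                                      # vox_offset
  wFlt(1); wFlt(0)                               # scl_slope, scl_inter
  wInt(0L, 2); writeBin(raw(1), con)             # slice_end, slice_code
  writeBin(as.raw(2L), con)                      # xyzt_units: mm
  wFlt(c(0, 0, 0, 0))                            # cal_max..toffset
  wInt(c(0L, 0L), 4)                             # glmax, glmin
  writeBin(padRaw(sprintf("tpi_h=%.10g", vol@timePostInjection), 80), con)
  writeBin(raw(24), con)                         # aux_file
  wInt(0L, 2); wInt(1L, 2)                       # qform_code=0, sform_code=1
  wFlt(rep(0, 6))                                # quatern/qoffset
  wFlt(c(vol@voxelSize, 0, 0, vol@origin[1]))    # srow_x
  wFlt(c(0, vol@voxelSize, 0, vol@origin[2]))    # srow_y
  wFlt(c(0, 0, vol@voxelSize, vol@origin[3]))    # srow_z
  writeBin(raw(16), con)                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)     # magic
  writeBin(raw(4), con)                          # extension flag
  writeBin(as.numeric(vol@voxels), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume as an ActivityVolume
#'
#' Supports single-file little- or big-endian NIfTI-1, 3-D, datatypes
#' int16/float32/float64, with scl_slope/scl_inter applied. Spacing is
#' taken from pixdim, origin from the sform translation column when
#' sform_code > 0. Negative intensities are clipped to zero (calibrated
#' activity concentrations cannot be negative); the acquisition time is
#' recovered from a \code{"tpi_h="} tag in descrip when present.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param timePostInjection acquisition time in hours; overrides any
#'   value recorded in the file header.
#' @return An \linkS4class{ActivityVolume}.
#' @export
readActivityVolume <- function(path, timePostInjection = NULL) {
  con <- niftiCon(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("not a NIfTI-1 file (short header)")
  rInt <- function(off, size, n = 1L, endian = "little")
    readBin(hdr[(off + 1L):(off + size * n)], "integer", n = n,
            size = size, endian = endian)
  rFlt <- function(off, n = 1L, endian = "little")
    readBin(hdr[(off + 1L):(off + 4L * n)], "numeric", n = n, size = 4L,
            endian = endian)
  endian <- "little"
  if (rInt(0, 4) != 348L) {
    if (rInt(0, 4, endian = "big") == 348L) endian <- "big"
    else stop("not a NIfTI-1 file (sizeof_hdr != 348)")
  }
  dimv <- rInt(40, 2, 8, endian)
  ndim <- dimv[1]
  if (ndim < 3L || any(dimv[5:8] > 1L))
    stop("only 3-D volumes are supported")
  d <- dimv[2:4]
  dtype <- rInt(70, 2, endian = endian)
  pixdim <- rFlt(76, 8, endian)
  voxOffset <- rFlt(108, endian = endian)
  sclSlope <- rFlt(112, endian = endian)
  sclInter <- rFlt(116, endian = endian)
  descrip <- rawToChar(hdr[149:228][hdr[149:228] != as.raw(0)])
  sformCode <- rInt(254, 2, endian = endian)
  origin <- c(0, 0, 0)
  if (sformCode > 0L)
    origin <- c(rFlt(280, 4, endian)[4], rFlt(296, 4, endian)[4],
                rFlt(312, 4, endian)[4])
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("missing NIfTI magic")
  nvox <- prod(d)
  skip <- voxOffset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  vals <- switch(as.character(dtype),
    "4" = readBin(con, "integer", n = nvox, size = 2L, endian = endian),
    "16" = readBin(con, "numeric", n = nvox, size = 4L, endian = endian),
    "64" = readBin(con, "numeric", n = nvox, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype: ", dtype))
  if (length(vals) < nvox) stop("truncated NIfTI data section")
  if (!is.na(sclSlope) && sclSlope != 0 && !(sclSlope == 1 && sclInter == 0))
    vals <- vals * sclSlope + sclInter
  vals <- pmax(vals, 0)
  vs <- pixdim[2]
  if (!isTRUE(all.equal(pixdim[2], pixdim[3], tolerance = 1e-4)) ||
      !isTRUE(all.equal(pixdim[2], pixdim[4], tolerance = 1e-4)))
    warning("anisotropic voxels; using pixdim[1] as isotropic size")
  tpi <- 0
  m <- regmatches(descrip, regexpr("tpi_h=([0-9.eE+-]+)", descrip))
  if (length(m)) tpi <- as.numeric(sub("tpi_h=", "", m))
  if (!is.null(timePostInjection)) tpi <- timePostInjection
  new("ActivityVolume", voxels = array(vals, dim = d), voxelSize = vs,
      origin = origin, timePostInjection = tpi)
}

setMethod("show", "ActivityVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ActivityVolume %dx%dx%d @ %.3g mm, t = %g h p.i.\n",
              d[1], d[2], d[3], object@voxelSize, object@timePostInjection))
  cat(sprintf("  total activity %.4g Bq, max %.4g Bq/ml\n",
              sum(object@voxels) * voxelVolumeMl(object),
              max(object@voxels)))
})

## voxel volume in ml (mm^3 / 1000)
voxelVolumeMl <- function(vol) {
  vs <- if (is(vol, "ActivityVolume")) vol@voxelSize else vol
  vs^3 / 1000
}
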