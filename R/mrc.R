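#' Read and write MRC2014 maps and image stacks
#'
#' Minimal MRC2014 support for the workflow's working currency: mode 2
#' (32-bit float) volumes and image stacks, little-endian. The pixel
#' size is taken from the cell dimensions divided by the grid sampling.
#' Stacks are recognized by `ispg == 0` with `mz == 1` (then `nz` is the
#' number of images); volumes carry `ispg == 1`.
#'
#' @param path File path.
#' @return `read_mrc()` returns a [density_map()] for volumes or an
#'   [image_stack()] for stacks.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ints1 <- readBin(con, "integer", 10, size = 4, endian = "little")
  cella <- readBin(con, "numeric", 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", 3, size = 4, endian = "little")
  mapcrs <- readBin(con, "integer", 3, size = 4, endian = "little")
  dstats <- readBin(con, "numeric", 3, size = 4, endian = "little")
  ispg <- readBin(con, "integer", 1, size = 4, endian = "little")
  nsymbt <- readBin(con, "integer", 1, size = 4, endian = "little")
  invisible(readBin(con, "raw", 4 * 25))             # extra words 25-49
  invisible(readBin(con, "numeric", 3, size = 4, endian = "little")) # origin
  invisible(readBin(con, "raw", 8))                  # MAP + machst
  invisible(readBin(con, "numeric", 1, size = 4, endian = "little")) # rms
  invisible(readBin(con, "raw", 4 + 800))            # nlabl + labels
  nx <- ints1[1]; ny <- ints1[2]; nz <- ints1[3]; mode <- ints1[4]
  mx <- ints1[8]; my <- ints1[9]; mz <- ints1[10]
  if (mode != 2) {
    stop("unsupported MRC mode ", mode, " (only mode 2, 32-bit float)",
         call. = FALSE)
  }
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    stop("unsupported MRC axis order (expect mapc,mapr,maps = 1,2,3)",
         call. = FALSE)
  }
  if (nsymbt > 0) invisible(readBin(con, "raw", nsymbt))
  n <- as.numeric(nx) * ny * nz
  vox <- readBin(con, "numeric", n, size = 4, endian = "little")
  arr <- array(vox, c(nx, ny, nz))
  pixel_size <- cella[1] / mx
  if (ispg == 0 && mz == 1) image_stack(arr, pixel_size) else density_map(arr, pixel_size)
}

#' @rdname read_mrc
#' @param x A [density_map()] or [image_stack()].
#' @return `write_mrc()` returns `path`, invisibly. Header min/max/mean
#'   and rms fields are recomputed from the voxel payload.
#' @export
write_mrc <- function(x, path) {
  stopifnot(inherits(x, c("density_map", "image_stack")))
  arr <- x$data
  d <- dim(arr)
  is_stack <- inherits(x, "image_stack")
  mz <- if (is_stack) 1L else d[3]
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(d[1], d[2], d[3], 2L, 0L, 0L, 0L, d[1], d[2], mz))
  wf(c(d[1], d[2], mz) * x$pixel_size)   # cella
  wf(c(90, 90, 90))                      # cellb
  wi(c(1L, 2L, 3L))
  wf(c(min(arr), max(arr), mean(arr)))
  wi(c(if (is_stack) 0L else 1L, 0L))    # ispg, nsymbt
  writeBin(raw(4 * 25), con)             # extra
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con) # machst little-endian
  wf(stats::sd(arr))                     # rms
  wi(0L)                                 # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(arr), con, size = 4, endian = "little")
  invisible(path)
}
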