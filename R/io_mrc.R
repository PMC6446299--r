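# MRC2014 image I/O. The header is 1024 bytes of int32/float32 words; image
# data follow with x fastest, then y, then z. Images are represented in R as
# matrices indexed [x + 1, y + 1] (0-based pixel coordinates (x, y) =
# (column, row) of the image); stacks are arrays dim c(nx, ny, n) with the
# image index last.

MRC_MODES <- c(`0` = "int8", `1` = "int16", `2` = "float32", `6` = "uint16")

#' Read an MRC2014 image or stack
#'
#' @param path path to an MRC file.
#' @return a list with elements `data` (matrix `nx` x `ny` for a single
#'   image, or array `c(nx, ny, nz)` for a stack, with a `pixel_size`
#'   attribute in Angstrom/pixel) and `header` (list with `nx`, `ny`, `nz`,
#'   `mode`, `pixel_size`).
#' @export
read_mrc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr_raw <- readBin(con, "raw", n = 1024)
  if (length(hdr_raw) < 1024) stop("corrupt header: file shorter than 1024 bytes")
  int_at <- function(word) {
    readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)], "integer", size = 4,
            endian = "little")
  }
  num_at <- function(word) {
    readBin(hdr_raw[(4 * (word - 1) + 1):(4 * word)], "numeric", size = 4,
            endian = "little")
  }
  nx <- int_at(1); ny <- int_at(2); nz <- int_at(3); mode <- int_at(4)
  if (is.na(nx) || nx < 1) stop("format error in field nx: ", nx)
  if (is.na(ny) || ny < 1) stop("format error in field ny: ", ny)
  if (is.na(nz) || nz < 1) stop("format error in field nz: ", nz)
  if (!as.character(mode) %in% names(MRC_MODES)) {
    stop("format error in field mode: unsupported mode ", mode)
  }
  mx <- int_at(8)
  cella_x <- num_at(11)
  pixel_size <- if (mx > 0 && is.finite(cella_x) && cella_x > 0) cella_x / mx else 1
  nsymbt <- int_at(24)
  if (is.na(nsymbt) || nsymbt < 0) nsymbt <- 0L
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))

  n_vox <- as.double(nx) * ny * nz
  vals <- switch(as.character(mode),
    `0` = as.double(readBin(con, "integer", n = n_vox, size = 1, signed = TRUE,
                            endian = "little")),
    `1` = as.double(readBin(con, "integer", n = n_vox, size = 2, signed = TRUE,
                            endian = "little")),
    `2` = readBin(con, "numeric", n = n_vox, size = 4, endian = "little"),
    `6` = as.double(readBin(con, "integer", n = n_vox, size = 2, signed = FALSE,
                            endian = "little"))
  )
  if (length(vals) < n_vox) stop("corrupt file: fewer data values than nx*ny*nz")
  data <- if (nz == 1) matrix(vals, nx, ny) else array(vals, c(nx, ny, nz))
  attr(data, "pixel_size") <- pixel_size
  list(data = data,
       header = list(nx = nx, ny = ny, nz = nz, mode = mode,
                     pixel_size = pixel_size))
}

#' Write an MRC2014 image or stack
#'
#' Data are written as 32-bit floats (MRC mode 2), little-endian, with the
#' pixel size recorded in the cell dimensions.
#'
#' @param path output path.
#' @param pixels matrix (single image) or array `c(nx, ny, n)` (stack);
#'   values must be finite.
#' @param pixel_size Angstrom per pixel (default: the `pixel_size` attribute
#'   of `pixels`, else 1).
#' @return invisibly, `path`.
#' @export
write_mrc <- function(path, pixels, pixel_size = NULL) {
  pixel_size <- pixel_size %||% attr(pixels, "pixel_size") %||% 1
  if (!all(is.finite(pixels))) stop("pixels must be finite")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  d <- dim(pixels)
  if (is.null(d) || !length(d) %in% c(2, 3)) stop("pixels must be 2D or 3D")
  nx <- d[1]; ny <- d[2]; nz <- if (length(d) == 3) d[3] else 1L
  vals <- as.numeric(pixels)

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wn <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, nz))                 # words 1-3
  wi(2)                             # mode 2: float32
  wi(c(0, 0, 0))                    # nxstart..nzstart
  wi(c(nx, ny, nz))                 # mx, my, mz
  wn(c(nx, ny, nz) * pixel_size)    # cella
  wn(c(90, 90, 90))                 # cellb
  wi(c(1, 2, 3))                    # mapc, mapr, maps
  wn(c(min(vals), max(vals), mean(vals)))  # dmin, dmax, dmean
  wi(0)                             # word 23: ispg (0 = image / stack)
  wi(0)                             # word 24: nsymbt
  wi(c(0, 0))                       # words 25-26: extra
  writeBin(raw(4), con)             # word 27: exttyp (none)
  wi(20140)                         # word 28: nversion (MRC2014)
  wi(rep(0L, 21))                   # words 29-49: extra
  wn(c(0, 0, 0))                    # words 50-52: origin
  writeBin(charToRaw("MAP "), con)  # word 53
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # word 54: machst (LE)
  wn(if (length(vals) > 1) stats::sd(vals) else 0)  # word 55: rms
  wi(0)                             # word 56: nlabl
  writeBin(raw(800), con)           # words 57-256: labels
  writeBin(vals, con, size = 4, endian = "little")
  invisible(path)
}
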