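# MRC2014 electron-microscopy stack I/O (modes 0, 1, 2, 6).
#
# The 1024-byte header is parsed field-by-field; dimensions come from header
# words 1-3 (nx, ny, nz) and the pixel type from word 4 (mode). Files are
# recognized by the "MAP " stamp at byte offset 208. Data follow the header
# (plus any extended header of `nsymbt` bytes) in x-fastest, then y, then z
# order, which matches R's column-major array layout directly.

.MRC_MODE_BYTES <- c("0" = 1L, "1" = 2L, "2" = 4L, "6" = 2L)

#' @noRd
.mrcIsMRC <- function(path) {
  if (!file.exists(path) || file.size(path) < 1024) return(FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 208)
  identical(readBin(con, "raw", 3), charToRaw("MAP"))
}

#' @noRd
.mrcRead <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1024)
  if (length(hdr) < 1024) stop("truncated MRC header in ", path)
  if (!identical(hdr[209:211], charToRaw("MAP")))
    stop("not an MRC2014 file (missing MAP stamp): ", path)
  # machine stamp: 0x44 0x44 little-endian, 0x11 0x11 big-endian
  endian <- if (as.integer(hdr[213]) %in% c(0x11)) "big" else "little"
  rd_i32 <- function(word) {  # 1-based header word index
    b <- hdr[((word - 1L) * 4L + 1L):(word * 4L)]
    if (endian == "big") b <- rev(b)
    v <- .rd_uint(b, 4, "little")
    if (v >= 2^31) v - 2^32 else v
  }
  nx <- rd_i32(1); ny <- rd_i32(2); nz <- rd_i32(3); mode <- rd_i32(4)
  nsymbt <- rd_i32(24)
  if (!(as.character(mode) %in% names(.MRC_MODE_BYTES)))
    stop(sprintf("unsupported MRC mode %d in %s (supported: 0, 1, 2, 6)",
                 mode, path))
  if (nx < 1 || ny < 1 || nz < 1)
    stop(sprintf("invalid MRC dimensions %d x %d x %d in %s", nx, ny, nz, path))
  bpp <- .MRC_MODE_BYTES[[as.character(mode)]]
  expected <- nx * ny * nz * bpp
  seek(con, 1024 + nsymbt)
  bytes <- readBin(con, "raw", expected)
  if (length(bytes) < expected)
    stop(sprintf(
      "truncated MRC pixel data in %s: expected %.0f bytes, got %.0f",
      path, expected, length(bytes)))
  data <- switch(as.character(mode),
    "0" = as.integer(bytes),                       # treated as unsigned 0..255
    "1" = {
      v <- .rd_uint(bytes, 2, endian)
      as.integer(ifelse(v >= 2^15, v - 2^16, v))   # signed int16
    },
    "2" = readBin(bytes, "double", n = nx * ny * nz, size = 4, endian = endian),
    "6" = as.integer(.rd_uint(bytes, 2, endian)))  # uint16
  dim(data) <- c(nx, ny, nz)
  list(nx = nx, ny = ny, nz = nz, mode = mode, data = data)
}

#' @noRd
.mrcWrite <- function(path, data, mode = 0L) {
  d <- dim(data)
  if (length(d) != 3L) stop("MRC data must be a 3-d array (nx, ny, nz)")
  mode <- as.integer(mode)
  if (!(as.character(mode) %in% names(.MRC_MODE_BYTES)))
    stop("unsupported MRC mode ", mode)
  con <- file(path, "wb")
  on.exit(close(con))
  i32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  f32 <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  i32(d)                      # nx, ny, nz
  i32(mode)                   # mode
  i32(c(0L, 0L, 0L))          # nxstart..nzstart
  i32(d)                      # mx, my, mz
  f32(c(d[1], d[2], d[3]))    # cella (angstroms; 1 A/voxel placeholder)
  f32(c(90, 90, 90))          # cellb
  i32(c(1L, 2L, 3L))          # mapc, mapr, maps
  rng <- range(as.numeric(data))
  f32(c(rng[1], rng[2], mean(as.numeric(data))))  # dmin, dmax, dmean
  i32(c(1L, 0L))              # ispg, nsymbt
  writeBin(raw(100), con)     # extra (words 26-50)
  f32(c(0, 0, 0))             # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  f32(stats::sd(as.numeric(data)))                   # rms
  i32(0L)                     # nlabl
  writeBin(raw(800), con)     # labels
  v <- as.vector(data)
  switch(as.character(mode),
    "0" = writeBin(as.raw(as.integer(v)), con),
    "1" = writeBin(.u16le(as.integer(v) %% 65536L), con),
    "2" = writeBin(as.numeric(v), con, size = 4, endian = "little"),
    "6" = writeBin(.u16le(as.integer(v)), con))
  invisible(path)
}
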