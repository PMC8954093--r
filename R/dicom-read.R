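# DICOM Part 10 parser for the files this package writes: explicit VR
# little-endian datasets, native or encapsulated pixel data. Used by the
# read-back validator and by the round-trip tests.

#' Parse a DICOM Part 10 file
#'
#' Reads the file meta group and the dataset of an explicit VR little-endian
#' Part 10 file. Native pixel data is returned as a raw vector; encapsulated
#' pixel data as a list of raw frames (the basic offset table item is parsed
#' and discarded).
#'
#' @param path file to parse.
#' @return list with components \code{meta} (named list of file meta values),
#'   \code{dataset} (named list keyed \code{"GGGG,EEEE"}, each element a
#'   \code{list(vr, value)}), \code{pixelData} (raw vector or NULL) and
#'   \code{frames} (list of raw vectors or NULL).
#' @export
readDicomInstance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sz <- file.size(path)
  if (sz < 132) stop("not a DICOM Part 10 file (too short): ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, 128)
  if (!identical(readBin(con, "raw", 4), charToRaw("DICM")))
    stop("not a DICOM Part 10 file (missing DICM magic): ", path)

  readElement <- function() {
    hdr <- readBin(con, "raw", 8)
    if (length(hdr) < 8) return(NULL)
    group <- .rd_uint(hdr[1:2], 2, "little")
    element <- .rd_uint(hdr[3:4], 2, "little")
    if (group == 0xFFFE) {  # item / delimiter: implicit structure
      len <- .rd_uint(hdr[5:8], 4, "little")
      return(list(group = group, element = element, vr = "", len = len))
    }
    vr <- rawToChar(hdr[5:6])
    if (vr %in% .VR_LONG) {
      len <- .rd_uint(readBin(con, "raw", 4), 4, "little")
    } else {
      len <- .rd_uint(hdr[7:8], 2, "little")
    }
    list(group = group, element = element, vr = vr, len = len)
  }

  decodeValue <- function(vr, bytes) {
    if (vr %in% .VR_TEXT) {
      s <- rawToChar(bytes[bytes != as.raw(0)])
      sub("[ ]+$", "", s)
    } else if (vr == "US") {
      as.integer(.rd_uint(bytes, 2, "little"))
    } else if (vr == "UL") {
      .rd_uint(bytes, 4, "little")
    } else if (vr %in% c("SS")) {
      v <- .rd_uint(bytes, 2, "little"); as.integer(ifelse(v >= 2^15, v - 2^16, v))
    } else if (vr %in% c("FL", "FD")) {
      readBin(bytes, "double", n = length(bytes) %/% ifelse(vr == "FL", 4, 8),
              size = ifelse(vr == "FL", 4, 8), endian = "little")
    } else bytes
  }

  # ---- file meta group (always explicit VR little-endian) ----
  e0 <- readElement()
  if (is.null(e0) || e0$group != 0x0002 || e0$element != 0x0000)
    stop("malformed file meta group in ", path)
  metaLen <- .rd_uint(readBin(con, "raw", 4), 4, "little")
  metaEnd <- seek(con, NA) + metaLen
  meta <- list()
  while (seek(con, NA) < metaEnd) {
    e <- readElement()
    if (is.null(e)) stop("truncated file meta group in ", path)
    bytes <- readBin(con, "raw", e$len)
    meta[[sprintf("%04X,%04X", e$group, e$element)]] <- decodeValue(e$vr, bytes)
  }
  ts <- meta[["0002,0010"]]
  if (is.null(ts)) stop("file meta group lacks a transfer syntax UID: ", path)
  if (!ts %in% c(.UID_EXPLICIT_VR_LE, .UID_JPEG_BASELINE))
    stop("unsupported transfer syntax ", ts, " in ", path)

  # ---- dataset ----
  dataset <- list()
  pixelData <- NULL
  frames <- NULL
  repeat {
    e <- readElement()
    if (is.null(e)) break
    key <- sprintf("%04X,%04X", e$group, e$element)
    if (e$group == 0x7FE0 && e$element == 0x0010) {
      if (e$len == 0xFFFFFFFF) {
        frames <- list()
        first <- TRUE
        repeat {
          it <- readElement()
          if (is.null(it)) stop("unterminated encapsulated pixel data in ", path)
          if (it$group == 0xFFFE && it$element == 0xE0DD) break
          if (!(it$group == 0xFFFE && it$element == 0xE000))
            stop("malformed encapsulated pixel data in ", path)
          payload <- readBin(con, "raw", it$len)
          if (length(payload) < it$len)
            stop(sprintf("truncated frame item in %s: expected %.0f bytes, got %d",
                         path, it$len, length(payload)))
          if (first) first <- FALSE  # basic offset table; discard
          else frames[[length(frames) + 1L]] <- payload
        }
        dataset[[key]] <- list(vr = e$vr, value = NULL)
      } else {
        pixelData <- readBin(con, "raw", e$len)
        if (length(pixelData) < e$len)
          stop(sprintf("truncated pixel data in %s: expected %.0f bytes, got %d",
                       path, e$len, length(pixelData)))
        dataset[[key]] <- list(vr = e$vr, value = NULL)
      }
    } else {
      bytes <- readBin(con, "raw", e$len)
      if (length(bytes) < e$len)
        stop(sprintf("truncated element (%s) in %s: expected %.0f bytes, got %d",
                     key, path, e$len, length(bytes)))
      dataset[[key]] <- list(vr = e$vr, value = decodeValue(e$vr, bytes))
    }
  }
  list(meta = meta, dataset = dataset, pixelData = pixelData, frames = frames)
}

# convenience: fetch a dataset value by tag key, NULL when absent
#' @noRd
.dsVal <- function(parsed, key) {
  el <- parsed$dataset[[key]]
  if (is.null(el)) NULL else el$value
}

# decode the native grayscale pixel payload of a volume instance back to an
# integer matrix (Columns x Rows, i.e. X by Y)
#' @noRd
.dcmDecodeNativeSlice <- function(parsed) {
  rows <- .dsVal(parsed, "0028,0010")
  cols <- .dsVal(parsed, "0028,0011")
  bits_alloc <- .dsVal(parsed, "0028,0100")
  raw <- parsed$pixelData
  n <- rows * cols
  v <- if (bits_alloc == 8) as.integer(raw[seq_len(n)])
       else as.integer(.rd_uint(raw[seq_len(2 * n)], 2, "little"))
  # payload is row-major (x fastest): fill a (X, Y) matrix directly
  matrix(v, nrow = cols, ncol = rows)
}
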