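# Minimal TIFF container I/O.
#
# Writer: classic little-endian TIFF; striped grayscale pages (8/16-bit,
# one strip per page) and tiled RGB pages (uncompressed or per-tile baseline
# JPEG), SubIFD-based reduced-resolution chains, ImageDescription (OME-XML).
# Reader: classic + BigTIFF, both byte orders, compression none / JPEG,
# follows SubIFDs. Only what the open microscopy containers written and
# ingested here require; anything else fails loudly.

.TIFF_TAGS <- c(
  NewSubfileType = 254L, ImageWidth = 256L, ImageLength = 257L,
  BitsPerSample = 258L, Compression = 259L, Photometric = 262L,
  ImageDescription = 270L, StripOffsets = 273L, SamplesPerPixel = 277L,
  RowsPerStrip = 278L, StripByteCounts = 279L, PlanarConfig = 284L,
  Software = 305L, TileWidth = 322L, TileLength = 323L, TileOffsets = 324L,
  TileByteCounts = 325L, SubIFDs = 330L, SampleFormat = 339L,
  JPEGTables = 347L
)

# ---- little-endian raw helpers ------------------------------------------

.u16le <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(x %% 256L, x %/% 256L))
}

.u32le <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  if (any(b3 > 255)) stop("uint32 overflow while writing TIFF offsets")
  as.raw(rbind(b0, b1, b2, b3))
}

.rd_uint <- function(raw, size, endian) {
  # raw vector whose length is a multiple of `size`; returns doubles
  m <- matrix(as.integer(raw), nrow = size)
  if (endian == "big") m <- m[size:1, , drop = FALSE]
  as.numeric(colSums(m * 256^(seq_len(size) - 1)))
}

# serialize pixel matrix/array to row-major interleaved bytes
.rasterBytes <- function(px, bits) {
  if (length(dim(px)) == 2L) v <- as.integer(t(px))
  else v <- as.integer(aperm(px, c(3L, 2L, 1L)))
  if (bits == 8L) as.raw(v)
  else if (bits == 16L) as.raw(rbind(v %% 256L, v %/% 256L))
  else stop("unsupported bits per sample: ", bits)
}

# ---- writer --------------------------------------------------------------

# page spec: list(pixels = [h,w] or [h,w,3] integer/raw array,
#   bits = 8|16, photometric = 0..6, compression = "none"|"jpeg",
#   quality = 0..100, tile_size = NULL or int, description = NULL or string,
#   software = NULL or string, subfiletype = 0|1, subifds = list(of specs))
.tiffEncodePage <- function(page) {
  px <- page$pixels
  if (is.raw(px)) { d <- dim(px); px <- array(as.integer(px), d) }
  d <- dim(px)
  h <- d[1]; w <- d[2]
  spp <- if (length(d) == 3L) d[3] else 1L
  bits <- if (is.null(page$bits)) 8L else as.integer(page$bits)
  comp <- if (is.null(page$compression)) "none" else page$compression
  if (comp == "jpeg" && (spp != 3L || bits != 8L))
    stop("JPEG-compressed pages must be 8-bit RGB")

  if (is.null(page$tile_size)) {
    segments <- list(.rasterBytes(px, bits))
    layout <- list(tiled = FALSE, rows_per_strip = h)
  } else {
    ts <- as.integer(page$tile_size)
    cols <- ceiling(w / ts); rows <- ceiling(h / ts)
    bg <- if (is.null(page$background)) rep(255L, spp) else as.integer(page$background)
    segments <- vector("list", cols * rows)
    k <- 1L
    for (ty in seq_len(rows)) {
      for (tx in seq_len(cols)) {
        y0 <- (ty - 1L) * ts + 1L; x0 <- (tx - 1L) * ts + 1L
        if (spp == 3L) {
          tile <- array(rep(bg, each = ts * ts), dim = c(ts, ts, 3L))
          ye <- min(h, y0 + ts - 1L); xe <- min(w, x0 + ts - 1L)
          tile[1:(ye - y0 + 1L), 1:(xe - x0 + 1L), ] <-
            px[y0:ye, x0:xe, , drop = FALSE]
        } else {
          tile <- matrix(bg[1], ts, ts)
          ye <- min(h, y0 + ts - 1L); xe <- min(w, x0 + ts - 1L)
          tile[1:(ye - y0 + 1L), 1:(xe - x0 + 1L)] <- px[y0:ye, x0:xe]
        }
        segments[[k]] <- if (comp == "jpeg") {
          q <- if (is.null(page$quality)) 90 else page$quality
          jpeg::writeJPEG(tile / 255, raw(), quality = q / 100)
        } else .rasterBytes(tile, bits)
        k <- k + 1L
      }
    }
    layout <- list(tiled = TRUE, tile_size = ts)
  }
  list(width = w, height = h, spp = spp, bits = bits,
       compression = if (comp == "jpeg") 7L else 1L,
       photometric = if (is.null(page$photometric)) {
         if (spp == 3L) { if (comp == "jpeg") 6L else 2L } else 1L
       } else as.integer(page$photometric),
       description = page$description, software = page$software,
       subfiletype = if (is.null(page$subfiletype)) 0L else as.integer(page$subfiletype),
       layout = layout, segments = segments,
       subifds = lapply(page$subifds, .tiffEncodePage))
}

# Build IFD entry table for an encoded page once offsets are known.
# Returns raw vector of the IFD block (count + entries + next pointer).
.tiffBuildIFD <- function(enc, seg_offsets, extval_offset, next_ifd,
                          subifd_offsets) {
  entries <- list()  # each: list(tag, type, count, raw4 or ext raw)
  ext <- raw(0)      # external value area, laid out at extval_offset
  add <- function(tag, type, values, ascii = FALSE) {
    if (ascii) {
      bytes <- c(charToRaw(values), as.raw(0L))
      count <- length(bytes)
    } else {
      bytes <- if (type == 3L) .u16le(values) else .u32le(values)
      count <- length(values)
    }
    if (length(bytes) <= 4L) {
      val4 <- c(bytes, raw(4L - length(bytes)))
      entries[[length(entries) + 1L]] <<- list(tag = tag, type = type,
                                               count = count, val = val4)
    } else {
      if (length(ext) %% 2L == 1L) ext <<- c(ext, as.raw(0L))
      off <- extval_offset + length(ext)
      ext <<- c(ext, bytes)
      entries[[length(entries) + 1L]] <<- list(tag = tag, type = type,
                                               count = count, val = .u32le(off))
    }
  }
  T <- .TIFF_TAGS
  if (enc$subfiletype != 0L) add(T[["NewSubfileType"]], 4L, enc$subfiletype)
  add(T[["ImageWidth"]], 4L, enc$width)
  add(T[["ImageLength"]], 4L, enc$height)
  add(T[["BitsPerSample"]], 3L, rep(enc$bits, enc$spp))
  add(T[["Compression"]], 3L, enc$compression)
  add(T[["Photometric"]], 3L, enc$photometric)
  if (!is.null(enc$description))
    add(T[["ImageDescription"]], 2L, enc$description, ascii = TRUE)
  add(T[["SamplesPerPixel"]], 3L, enc$spp)
  if (enc$layout$tiled) {
    add(T[["TileWidth"]], 4L, enc$layout$tile_size)
    add(T[["TileLength"]], 4L, enc$layout$tile_size)
    add(T[["TileOffsets"]], 4L, seg_offsets)
    add(T[["TileByteCounts"]], 4L, vapply(enc$segments, length, 1L))
  } else {
    add(T[["StripOffsets"]], 4L, seg_offsets)
    add(T[["RowsPerStrip"]], 4L, enc$layout$rows_per_strip)
    add(T[["StripByteCounts"]], 4L, vapply(enc$segments, length, 1L))
  }
  add(T[["PlanarConfig"]], 3L, 1L)
  if (!is.null(enc$software)) add(T[["Software"]], 2L, enc$software, ascii = TRUE)
  if (length(subifd_offsets)) add(T[["SubIFDs"]], 4L, subifd_offsets)
  ord <- order(vapply(entries, function(e) e$tag, 1L))
  entries <- entries[ord]
  tbl <- c(.u16le(length(entries)),
           unlist(lapply(entries, function(e)
             c(.u16le(e$tag), .u16le(e$type), .u32le(e$count), e$val))),
           .u32le(next_ifd))
  list(ifd = tbl, ext = ext)
}

# size of the IFD table for an encoded page (entries are deterministic)
.tiffIFDSize <- function(enc, n_subifds) {
  n <- 9L  # width,length,bps,comp,photo,spp,planar + 2 layout offset/count tags
  n <- n + if (enc$layout$tiled) 2L else 1L  # tilewidth+tilelength vs rowsperstrip
  if (enc$subfiletype != 0L) n <- n + 1L
  if (!is.null(enc$description)) n <- n + 1L
  if (!is.null(enc$software)) n <- n + 1L
  if (n_subifds > 0L) n <- n + 1L
  2L + n * 12L + 4L
}

# conservative upper bound for the external value area
.tiffExtSize <- function(enc) {
  sz <- 0L
  nseg <- length(enc$segments)
  if (nseg > 1L) sz <- sz + 2L * (4L * nseg) + 2L
  if (enc$spp > 1L) sz <- sz + 2L * enc$spp + 2L
  nsub <- length(enc$subifds)
  if (nsub > 1L) sz <- sz + 4L * nsub + 2L
  if (!is.null(enc$description)) sz <- sz + nchar(enc$description, "bytes") + 3L
  if (!is.null(enc$software)) sz <- sz + nchar(enc$software, "bytes") + 3L
  sz + 8L
}

#' @noRd
.tiffWrite <- function(path, pages) {
  encs <- lapply(pages, .tiffEncodePage)
  # flatten: each node gets segment area, ext area, ifd table; assign offsets
  flat <- list()
  walk <- function(enc) {
    idx <- length(flat) + 1L
    enc$children <- integer(0)
    flat[[idx]] <<- enc
    for (s in enc$subifds) {
      ci <- walk(s)
      flat[[idx]]$children <<- c(flat[[idx]]$children, ci)
    }
    idx
  }
  top <- vapply(encs, walk, 1L)

  pad2 <- function(x) x + x %% 2
  cur <- 8
  for (i in seq_along(flat)) {
    segsz <- vapply(flat[[i]]$segments, length, 1L)
    offs <- numeric(length(segsz))
    for (k in seq_along(segsz)) { offs[k] <- cur; cur <- pad2(cur + segsz[k]) }
    flat[[i]]$seg_offsets <- offs
    flat[[i]]$ext_offset <- cur
    cur <- pad2(cur + .tiffExtSize(flat[[i]]))
    flat[[i]]$ifd_offset <- cur
    cur <- pad2(cur + .tiffIFDSize(flat[[i]], length(flat[[i]]$subifds)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), .u16le(42L), .u32le(flat[[top[1]]]$ifd_offset)), con)
  pos <- 8
  put <- function(bytes, at) {
    if (at > pos) writeBin(raw(at - pos), con)
    writeBin(bytes, con)
    pos <<- at + length(bytes)
  }
  for (i in seq_along(flat)) {
    enc <- flat[[i]]
    for (k in seq_along(enc$segments)) put(enc$segments[[k]], enc$seg_offsets[k])
    nxt <- 0
    if (i %in% top) {
      j <- match(i, top)
      if (j < length(top)) nxt <- flat[[top[j + 1L]]]$ifd_offset
    }
    sub_off <- vapply(enc$children, function(ci) flat[[ci]]$ifd_offset, 1)
    built <- .tiffBuildIFD(enc, enc$seg_offsets, enc$ext_offset, nxt, sub_off)
    if (length(built$ext) > .tiffExtSize(enc) ||
        length(built$ifd) > .tiffIFDSize(enc, length(enc$subifds)))
      stop("internal error: TIFF block size underestimated")
    if (length(built$ext)) put(built$ext, enc$ext_offset)
    put(built$ifd, enc$ifd_offset)
  }
  invisible(path)
}

# ---- reader --------------------------------------------------------------

.tiffReadHeader <- function(con) {
  seek(con, 0)
  magic <- readBin(con, "raw", 4)
  endian <- if (identical(magic[1:2], charToRaw("II"))) "little"
            else if (identical(magic[1:2], charToRaw("MM"))) "big"
            else stop("not a TIFF file (bad byte-order mark)")
  ver <- .rd_uint(magic[3:4], 2, endian)
  if (ver == 42) {
    first <- .rd_uint(readBin(con, "raw", 4), 4, endian)
    list(endian = endian, big = FALSE, first_ifd = first)
  } else if (ver == 43) {
    sz <- .rd_uint(readBin(con, "raw", 4), 2, endian)  # offset size + pad
    if (sz %% 256 != 8) stop("unsupported BigTIFF offset size")
    first <- .rd_uint(readBin(con, "raw", 8), 8, endian)
    list(endian = endian, big = TRUE, first_ifd = first)
  } else stop("not a TIFF file (bad version ", ver, ")")
}

.TIFF_TYPE_SIZE <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L, 4L, 0L, 0L, 8L, 8L, 8L)

.tiffReadIFD <- function(con, offset, hdr) {
  seek(con, offset)
  n <- if (hdr$big) .rd_uint(readBin(con, "raw", 8), 8, hdr$endian)
       else .rd_uint(readBin(con, "raw", 2), 2, hdr$endian)
  esz <- if (hdr$big) 20L else 12L
  entries_raw <- readBin(con, "raw", n * esz)
  next_off <- .rd_uint(readBin(con, "raw", if (hdr$big) 8L else 4L),
                       if (hdr$big) 8L else 4L, hdr$endian)
  tags <- list()
  for (i in seq_len(n)) {
    e <- entries_raw[((i - 1L) * esz + 1L):(i * esz)]
    tag <- .rd_uint(e[1:2], 2, hdr$endian)
    type <- .rd_uint(e[3:4], 2, hdr$endian)
    if (type < 1 || type > 18 || .TIFF_TYPE_SIZE[type] == 0L) next
    count <- .rd_uint(e[if (hdr$big) 5:12 else 5:8], if (hdr$big) 8 else 4, hdr$endian)
    vsz <- .TIFF_TYPE_SIZE[type] * count
    inline <- if (hdr$big) 8L else 4L
    if (vsz <= inline) {
      vraw <- e[(esz - inline + 1L):(esz - inline + vsz)]
    } else {
      voff <- .rd_uint(e[(esz - inline + 1L):esz], inline, hdr$endian)
      here <- seek(con, NA)
      seek(con, voff)
      vraw <- readBin(con, "raw", vsz)
      seek(con, here)
    }
    val <- switch(as.character(type),
      "2" = rawToChar(vraw[vraw != as.raw(0)]),
      "1" = , "6" = , "7" = as.numeric(as.integer(vraw)),
      "3" = .rd_uint(vraw, 2, hdr$endian),
      "4" = , "13" = .rd_uint(vraw, 4, hdr$endian),
      "16" = , "18" = .rd_uint(vraw, 8, hdr$endian),
      "5" = {  # RATIONAL
        u <- .rd_uint(vraw, 4, hdr$endian)
        u[seq(1, length(u), 2)] / pmax(1, u[seq(2, length(u), 2)])
      },
      NULL)
    if (!is.null(val)) tags[[as.character(tag)]] <- val
  }
  list(tags = tags, next_offset = next_off)
}

.tg <- function(tags, name, default = NULL) {
  v <- tags[[as.character(.TIFF_TAGS[[name]])]]
  if (is.null(v)) default else v
}

.tiffDecodePage <- function(con, tags, hdr, path = "") {
  w <- .tg(tags, "ImageWidth"); h <- .tg(tags, "ImageLength")
  if (is.null(w) || is.null(h)) stop("TIFF IFD missing image dimensions")
  spp <- .tg(tags, "SamplesPerPixel", 1)
  bits <- .tg(tags, "BitsPerSample", 8)[1]
  comp <- .tg(tags, "Compression", 1)
  if (!comp %in% c(1, 7))
    stop(sprintf("unsupported TIFF compression %d in %s", comp, path))
  tiled <- !is.null(.tg(tags, "TileOffsets"))
  if (tiled) {
    ts_w <- .tg(tags, "TileWidth"); ts_h <- .tg(tags, "TileLength")
    offs <- .tg(tags, "TileOffsets"); cnts <- .tg(tags, "TileByteCounts")
    cols <- ceiling(w / ts_w); rows <- ceiling(h / ts_h)
    if (length(offs) != cols * rows)
      stop(sprintf("TIFF tile count mismatch in %s: expected %d, found %d",
                   path, cols * rows, length(offs)))
  } else {
    offs <- .tg(tags, "StripOffsets"); cnts <- .tg(tags, "StripByteCounts")
    rps <- .tg(tags, "RowsPerStrip", h)
  }
  out <- array(0L, dim = c(h, w, spp))
  readSeg <- function(off, cnt) {
    seek(con, off)
    bytes <- readBin(con, "raw", cnt)
    if (length(bytes) < cnt)
      stop(sprintf("truncated TIFF data in %s: expected %d bytes, got %d",
                   path, cnt, length(bytes)))
    bytes
  }
  decodeRaster <- function(bytes, sw, sh) {
    if (comp == 7) {
      img <- jpeg::readJPEG(bytes)
      if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
      storage.mode(img) <- "double"
      array(as.integer(round(img * 255)), dim = dim(img))
    } else {
      n <- sw * sh * spp
      v <- if (bits == 8) as.integer(bytes[seq_len(n)])
           else as.integer(.rd_uint(bytes[seq_len(2 * n)], 2, hdr$endian))
      # bytes are row-major interleaved: index (c, x, y)
      aperm(array(v, dim = c(spp, sw, sh)), c(3L, 2L, 1L))
    }
  }
  if (tiled) {
    k <- 1L
    for (ty in seq_len(rows)) {
      for (tx in seq_len(cols)) {
        tile <- decodeRaster(readSeg(offs[k], cnts[k]), ts_w, ts_h)
        y0 <- (ty - 1) * ts_h + 1; x0 <- (tx - 1) * ts_w + 1
        ye <- min(h, y0 + ts_h - 1); xe <- min(w, x0 + ts_w - 1)
        out[y0:ye, x0:xe, ] <- tile[1:(ye - y0 + 1), 1:(xe - x0 + 1), , drop = FALSE]
        k <- k + 1L
      }
    }
  } else {
    y0 <- 1
    for (k in seq_along(offs)) {
      sh <- min(rps, h - y0 + 1)
      strip <- decodeRaster(readSeg(offs[k], cnts[k]), w, sh)
      out[y0:(y0 + sh - 1), , ] <- strip
      y0 <- y0 + sh
    }
  }
  if (spp == 1L) dim(out) <- dim(out)[1:2]
  out
}

# Parse a TIFF file. Returns list(pages = list of
#   list(tags, width, height, spp, bits, description, subifds = list(...),
#        pixels if decode)), header info.
#' @noRd
.tiffRead <- function(path, decode = TRUE, max_pages = Inf) {
  if (!file.exists(path)) stop("cannot read TIFF: no such file: ", path)
  if (file.size(path) == 0) stop("zero-byte file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- .tiffReadHeader(con)
  pages <- list()
  off <- hdr$first_ifd
  parseNode <- function(offset) {
    node <- .tiffReadIFD(con, offset, hdr)
    tags <- node$tags
    page <- list(
      tags = tags,
      width = .tg(tags, "ImageWidth"),
      height = .tg(tags, "ImageLength"),
      spp = .tg(tags, "SamplesPerPixel", 1),
      bits = .tg(tags, "BitsPerSample", 8)[1],
      tiled = !is.null(.tg(tags, "TileOffsets")),
      description = .tg(tags, "ImageDescription"),
      software = .tg(tags, "Software"),
      next_offset = node$next_offset
    )
    sub <- .tg(tags, "SubIFDs")
    page$subifds <- lapply(sub, function(so) parseNode(so))
    if (decode) page$pixels <- .tiffDecodePage(con, tags, hdr, path)
    page
  }
  while (off != 0 && length(pages) < max_pages) {
    page <- parseNode(off)
    pages[[length(pages) + 1L]] <- page
    off <- page$next_offset
  }
  list(pages = pages, endian = hdr$endian, big = hdr$big)
}
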