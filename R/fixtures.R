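# Deterministic synthetic fixture generator: one emitter per input class the
# converters accept (confocal-like multichannel z-stack OME-TIFF, serial EM
# stack as multi-page TIFF or MRC2014, pyramidal RGB whole-slide OME-TIFF).
# Texture content only has to be non-constant and smooth enough that JPEG
# round-trip error assertions are meaningful; all geometry is exact and all
# bytes are reproducible for equal arguments (seeded, no timestamps).

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

.FLUOR_NAMES <- c("DAPI", "FITC", "TRITC", "Cy5", "Cy7", "SHG")

#' Generate a confocal-like multichannel z-stack OME-TIFF
#'
#' Per-channel Gaussian blob textures over a z-profile, written as a
#' grayscale multi-page OME-TIFF in XYCZT plane order (channel fastest) with
#' channel names, illumination type, magnification and wavelengths in the
#' OME-XML. Output bytes are identical for identical arguments.
#'
#' @param channels number of channels (>= 1).
#' @param zPlanes number of optical sections (>= 1).
#' @param xy edge length of the square XY field in pixels (>= 16).
#' @param bitDepth 8, 12 or 16.
#' @param seed RNG seed controlling the texture.
#' @param path output file; default a tempfile ending in \code{.ome.tiff}.
#' @return the output path, invisibly.
#' @export
makeClsmVolume <- function(channels, zPlanes, xy = 64L, bitDepth = 16L,
                           seed = 1L, path = tempfile(fileext = ".ome.tiff")) {
  stopifnot(channels >= 1L, zPlanes >= 1L, xy >= 16L)
  if (!(bitDepth %in% c(8L, 12L, 16L)))
    stop("bitDepth: must be one of 8, 12, 16")
  channels <- as.integer(channels); zPlanes <- as.integer(zPlanes)
  xy <- as.integer(xy)
  maxv <- 2^bitDepth - 1
  .withSeed(seed, {
    chinfo <- lapply(seq_len(channels), function(c) {
      nm <- .FLUOR_NAMES[(c - 1L) %% length(.FLUOR_NAMES) + 1L]
      ChannelInfo(channelID = sprintf("Channel:0:%d", c - 1L),
                  channelName = nm, illuminationType = "Epifluorescence",
                  magnification = "63x",
                  emissionWavelength = 420 + 40 * c,
                  excitationWavelength = 350 + 40 * c)
    })
    blobs <- lapply(seq_len(channels), function(c)
      data.frame(cx = runif(4, 1, xy), cy = runif(4, 1, xy),
                 cz = runif(4, 1, zPlanes + 0.5), s = runif(4, xy / 10, xy / 5),
                 sz = runif(4, max(1, zPlanes / 6), max(2, zPlanes / 3)),
                 a = runif(4, 0.4, 0.9)))
    xs <- seq_len(xy); ys <- seq_len(xy)
    pages <- vector("list", channels * zPlanes)
    i <- 1L
    for (z in seq_len(zPlanes)) for (c in seq_len(channels)) {
      b <- blobs[[c]]
      img <- matrix(0, xy, xy)  # [y, x] page raster
      for (k in seq_len(nrow(b)))
        img <- img + b$a[k] * exp(-(z - b$cz[k])^2 / (2 * b$sz[k]^2)) *
          outer(exp(-(ys - b$cy[k])^2 / (2 * b$s[k]^2)),
                exp(-(xs - b$cx[k])^2 / (2 * b$s[k]^2)))
      img <- img + matrix(runif(xy * xy, 0, 0.02), xy, xy)
      pages[[i]] <- matrix(as.integer(round(pmin(img, 1) * maxv)), xy, xy)
      i <- i + 1L
    }
    ome <- .omeBuildVolumeXML(
      sizeX = xy, sizeY = xy, sizeC = channels, sizeZ = zPlanes, sizeT = 1L,
      type = if (bitDepth == 8L) "uint8" else "uint16",
      significantBits = bitDepth, physicalSize = c(0.25, 0.25, 1.0),
      channels = chinfo, name = "synthetic-clsm")
    specs <- lapply(seq_along(pages), function(k)
      list(pixels = pages[[k]], bits = if (bitDepth == 8L) 8L else 16L,
           photometric = 1L,
           description = if (k == 1L) ome else NULL))
    .tiffWrite(path, specs)
  })
  invisible(path)
}

#' Generate a serial EM section stack (multi-page TIFF or MRC2014)
#'
#' Speckle-textured 2D sections with a drifting gradient per slice. The MRC
#' container gets a valid MRC2014 header (nx/ny/nz header words, mode, MAP
#' stamp); mode 0 is the 8-bit default, modes 1/2/6 exercise the other
#' supported pixel types.
#'
#' @param nSlices number of sections (>= 1).
#' @param xy edge length of the square section in pixels.
#' @param container \code{"tiff"} or \code{"mrc"}.
#' @param seed RNG seed.
#' @param mode MRC mode (0, 1, 2 or 6); ignored for TIFF output.
#' @param path output file; default tempfile with matching extension.
#' @return the output path, invisibly.
#' @export
makeEmStack <- function(nSlices, xy = 32L, container = c("tiff", "mrc"),
                        seed = 1L, mode = 0L,
                        path = NULL) {
  container <- match.arg(container)
  stopifnot(nSlices >= 1L, xy >= 8L)
  nSlices <- as.integer(nSlices); xy <- as.integer(xy)
  if (is.null(path))
    path <- tempfile(fileext = if (container == "tiff") ".tif" else ".mrc")
  .withSeed(seed, {
    vol <- array(0L, dim = c(xy, xy, nSlices))
    xs <- seq_len(xy) / xy
    for (z in seq_len(nSlices)) {
      grad <- outer(xs, xs, function(a, b) 0.5 + 0.3 * sin(6 * a + z / 7) * cos(5 * b))
      speck <- matrix(runif(xy * xy, -0.12, 0.12), xy, xy)
      img <- pmin(pmax(grad + speck, 0), 1)
      vol[, , z] <- as.integer(round(t(img) * 255))  # [x, y]
    }
    if (container == "mrc") {
      data <- switch(as.character(mode),
        "0" = vol,
        "1" = vol * 128L,
        "2" = array(vol / 255, dim(vol)),
        "6" = vol * 257L,
        stop("unsupported MRC mode ", mode))
      .mrcWrite(path, data, mode = mode)
    } else {
      specs <- lapply(seq_len(nSlices), function(z)
        list(pixels = t(vol[, , z]), bits = 8L, photometric = 1L))
      .tiffWrite(path, specs)
    }
  })
  invisible(path)
}

# smooth H&E-like RGB texture sampled in base-level coordinates so that
# every pyramid level renders the same scene at its own scale
.wsiTexture <- function(w, h, scale, phase, base_w, base_h) {
  # coordinates in base space, normalized to [0, 1]
  u <- (seq_len(w) - 0.5) * scale / base_w
  v <- (seq_len(h) - 0.5) * scale / base_h
  f1 <- outer(sin(9 * pi * v + phase), cos(7 * pi * u))        # tissue bands
  f2 <- outer(cos(15 * pi * v - phase / 2), sin(13 * pi * u + phase))
  tissue <- pmax(f1 * 0.6 + f2 * 0.4, 0)                        # [h, w]
  r <- 255 - 90 * tissue
  g <- 255 - 160 * tissue
  b <- 255 - 60 * tissue
  px <- array(0L, dim = c(h, w, 3L))
  px[, , 1] <- as.integer(round(r))
  px[, , 2] <- as.integer(round(g))
  px[, , 3] <- as.integer(round(b))
  px
}

#' Generate a pyramidal RGB whole-slide OME-TIFF
#'
#' Writes a tiled RGB pyramid with an H&E-like smooth texture on a white
#' background: one main IFD per focal plane, reduced levels as SubIFDs,
#' level k dimensions \code{floor(base / ratio^k)}. Focal planes share the
#' scene geometry but differ in texture phase. With \code{omexml = FALSE}
#' (and a single level) the output is a bare tiled RGB TIFF, the shape the
#' sniffer classifies as \code{unrecognized_pyramid}.
#'
#' @param nLevels number of stored resolution levels (>= 1).
#' @param levelRatio per-axis shrink factor between adjacent levels (2 or 4).
#' @param baseWH integer length-2: base level width and height.
#' @param zPlanes number of focal planes.
#' @param seed RNG seed (texture phases).
#' @param omexml write OME-XML metadata (default TRUE).
#' @param tileSize TIFF tile edge (default 512).
#' @param path output file; default a tempfile ending in \code{.ome.tiff}.
#' @return the output path, invisibly.
#' @export
makeWsiPyramid <- function(nLevels, levelRatio = 4L, baseWH = c(2048L, 1024L),
                           zPlanes = 1L, seed = 1L, omexml = TRUE,
                           tileSize = 512L,
                           path = tempfile(fileext = ".ome.tiff")) {
  stopifnot(nLevels >= 1L, zPlanes >= 1L, length(baseWH) == 2L)
  if (!(levelRatio %in% c(2L, 4L))) stop("levelRatio: must be 2 or 4")
  dims <- lapply(seq_len(nLevels) - 1L, function(k)
    c(floor(baseWH[1] / levelRatio^k), floor(baseWH[2] / levelRatio^k)))
  if (any(unlist(dims) < 1L))
    stop(sprintf("degenerate smallest level %d x %d: increase baseWH or reduce nLevels",
                 dims[[nLevels]][1], dims[[nLevels]][2]))
  .withSeed(seed, {
    phases <- runif(zPlanes, 0, 2 * pi)
    ome <- .omeBuildPyramidXML(sizeX = baseWH[1], sizeY = baseWH[2],
                               sizeZ = zPlanes, name = "synthetic-wsi",
                               nLevels = nLevels)
    pages <- lapply(seq_len(zPlanes), function(z) {
      lv <- lapply(seq_len(nLevels), function(li) {
        d <- dims[[li]]
        px <- .wsiTexture(d[1], d[2], levelRatio^(li - 1L), phases[z],
                          baseWH[1], baseWH[2])
        dpx <- dim(px)
        px <- as.raw(px); dim(px) <- dpx  # pack: pyramids can be large
        px
      })
      subs <- if (nLevels > 1L)
        lapply(lv[-1], function(px)
          list(pixels = px, bits = 8L, tile_size = tileSize, subfiletype = 1L))
      else list()
      list(pixels = lv[[1]], bits = 8L, tile_size = tileSize,
           description = if (z == 1L && omexml) ome else NULL,
           subifds = subs)
    })
    .tiffWrite(path, pages)
  })
  invisible(path)
}
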