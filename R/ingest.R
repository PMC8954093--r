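# Ingestion: classify a source file by its magic/structure, read supported
# open containers into the in-memory model, and provide the pyramidal
# OME-TIFF fallback for flat tiled TIFFs whose reduced-resolution levels are
# absent or unreadable.

#' Classification of an input file
#'
#' Result of structure sniffing: the detected kind drives pipeline dispatch.
#' Classification reads file magic and container structure, never the file
#' extension.
#'
#' @slot path Filesystem location.
#' @slot detectedKind One of \code{"volume"}, \code{"em_stack"},
#'   \code{"pyramid"}, \code{"unrecognized_pyramid"}.
#' @slot formatName Short text name of the recognized container.
#' @export
setClass("SourceDescriptor",
  representation(path = "character", detectedKind = "character",
                 formatName = "character"),
  validity = function(object) {
    kinds <- c("volume", "em_stack", "pyramid", "unrecognized_pyramid")
    if (!(object@detectedKind %in% kinds))
      return(paste("detectedKind: must be one of", paste(kinds, collapse = ", ")))
    TRUE
  }
)

setMethod("show", "SourceDescriptor", function(object) {
  cat(sprintf("SourceDescriptor: %s [%s] %s\n", object@detectedKind,
              object@formatName, object@path))
})

.formatError <- function(...) {
  stop(errorCondition(sprintf(...), class = c("dicomizer_format_error", "error")))
}

# 2x2 area-average downsampling with floor(dim/2) output; deterministic
# round-half-up on the 4-pixel mean
#' @noRd
.areaHalve <- function(arr) {
  d <- dim(arr)
  h2 <- d[1] %/% 2L; w2 <- d[2] %/% 2L
  if (h2 < 1L || w2 < 1L) stop("cannot halve a dimension below 1 pixel")
  a <- arr[seq_len(2L * h2), seq_len(2L * w2), , drop = FALSE]
  odd_r <- seq(1L, 2L * h2, 2L); ev_r <- odd_r + 1L
  s <- a[odd_r, , , drop = FALSE] + a[ev_r, , , drop = FALSE]
  odd_c <- seq(1L, 2L * w2, 2L); ev_c <- odd_c + 1L
  s <- s[, odd_c, , drop = FALSE] + s[, ev_c, , drop = FALSE]
  array(as.integer((s + 2L) %/% 4L), dim = c(h2, w2, d[3]))
}

#' Classify an input file by structure
#'
#' Sniffs magic bytes and container structure: MRC2014 files (MAP stamp) are
#' electron-microscopy stacks; grayscale TIFFs are volumes (multi-page gray
#' without OME metadata is a serial-section stack); RGB TIFFs carrying
#' OME-XML or readable reduced-resolution pages are pyramids; a tiled RGB
#' TIFF with neither is classified \code{unrecognized_pyramid} and routed to
#' \code{\link{pyramidalize}}. A directory of PNG slices is a volume.
#'
#' @param path file (or slice directory) to classify.
#' @return a \linkS4class{SourceDescriptor}.
#' @export
sniffSource <- function(path) {
  if (!file.exists(path)) stop("cannot read input (no such path): ", path)
  if (dir.exists(path)) {
    pngs <- list.files(path, pattern = "\\.png$", ignore.case = TRUE)
    if (length(pngs) == 0L)
      .formatError("directory contains no PNG slices: %s", path)
    return(new("SourceDescriptor", path = path, detectedKind = "volume",
               formatName = "png-stack"))
  }
  if (file.access(path, 4) != 0) stop("cannot read input (permission): ", path)
  if (file.size(path) == 0) .formatError("zero-byte file: %s", path)
  if (.mrcIsMRC(path))
    return(new("SourceDescriptor", path = path, detectedKind = "em_stack",
               formatName = "mrc"))
  magic <- readBin(path, "raw", 4)
  if (!(identical(magic[1:2], charToRaw("II")) ||
        identical(magic[1:2], charToRaw("MM"))))
    .formatError("unrecognized file format (not TIFF, MRC or PNG stack): %s", path)

  tf <- tryCatch(.tiffRead(path, decode = FALSE),
                 error = function(e) .formatError("unreadable TIFF: %s (%s)",
                                                 path, conditionMessage(e)))
  pages <- tf$pages
  ome <- .omeParse(pages[[1]]$description)
  is_ome <- !is.null(ome)
  spp <- pages[[1]]$spp
  if (spp == 1L) {
    kind <- if (!is_ome && length(pages) > 1L) "em_stack" else "volume"
    return(new("SourceDescriptor", path = path, detectedKind = kind,
               formatName = if (is_ome) "ome-tiff" else "tiff"))
  }
  # RGB: pyramid if reduced-resolution levels are present and readable, or if
  # OME metadata declares the image
  widths <- vapply(pages, function(p) p$width, 1)
  nsub <- length(pages[[1]]$subifds)
  reducedReadable <- function() {
    reduced <- if (nsub > 0L) pages[[1]]$subifds
               else if (length(pages) > 1L) pages[-1] else list()
    if (length(reduced) == 0L) return(FALSE)
    ok <- vapply(reduced, function(p) {
      comp <- .tg(p$tags, "Compression", 1)
      has_data <- !is.null(.tg(p$tags, "TileOffsets")) ||
                  !is.null(.tg(p$tags, "StripOffsets"))
      comp %in% c(1, 7) && has_data && !is.null(p$width) && p$width >= 1
    }, TRUE)
    all(ok) && (nsub > 0L || all(diff(widths) < 0))
  }
  if (is_ome || reducedReadable())
    return(new("SourceDescriptor", path = path, detectedKind = "pyramid",
               formatName = if (is_ome) "ome-tiff" else "tiff"))
  new("SourceDescriptor", path = path, detectedKind = "unrecognized_pyramid",
      formatName = "tiff")
}

#' Read a confocal-like volume or EM stack into an ImageVolume
#'
#' Accepts multichannel z-stack OME-TIFFs (plane order C-fastest per the
#' XYCZT dimension order), plain grayscale TIFF stacks, MRC2014 stacks and
#' directories of PNG slices (lexicographic filename order). Pixels are
#' reordered to the internal X,Y,C,Z,T axis order; EM stacks get C = T = 1.
#'
#' @param path input file or slice directory.
#' @return an \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
  desc <- sniffSource(path)
  if (!desc@detectedKind %in% c("volume", "em_stack"))
    .formatError("not a volume or EM stack (detected %s): %s",
                 desc@detectedKind, path)
  src <- basename(path)

  if (desc@formatName == "png-stack") {
    files <- list.files(path, pattern = "\\.png$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files))]
    slices <- lapply(files, function(f) {
      px <- png::readPNG(f)
      if (length(dim(px)) == 3L) px <- px[, , 1]
      t(array(as.integer(round(px * 255)), dim = dim(px)))  # [x, y]
    })
    d <- dim(slices[[1]])
    if (!all(vapply(slices, function(s) identical(dim(s), d), TRUE)))
      .formatError("PNG slices disagree in dimensions under %s", path)
    px <- array(0L, dim = c(d[1], d[2], 1L, length(slices), 1L))
    for (i in seq_along(slices)) px[, , 1L, i, 1L] <- slices[[i]]
    return(ImageVolume(px, bitDepth = 8L, sourceName = src))
  }

  if (desc@formatName == "mrc") {
    m <- .mrcRead(path)
    depth <- c("0" = 8L, "1" = 16L, "2" = 16L, "6" = 16L)[[as.character(m$mode)]]
    data <- m$data
    if (m$mode == 2) {  # float: min-max rescale into the 16-bit range
      rng <- range(data)
      data <- if (diff(rng) == 0) array(0L, dim(data))
              else array(as.integer(round((data - rng[1]) / diff(rng) * 65535)),
                         dim(data))
    } else if (m$mode == 1 && min(data) < 0L) {
      data <- data - min(data)  # shift signed data to the unsigned range
    }
    px <- array(as.integer(data), dim = c(m$nx, m$ny, 1L, m$nz, 1L))
    return(ImageVolume(px, bitDepth = depth, sourceName = src))
  }

  tf <- .tiffRead(path, decode = TRUE)
  pages <- tf$pages
  ome <- .omeParse(pages[[1]]$description)
  planes <- lapply(pages, function(p) {
    if (length(dim(p$pixels)) == 3L) p$pixels[, , 1] else p$pixels
  })
  d <- dim(planes[[1]])
  X <- d[2]; Y <- d[1]
  if (is.null(ome)) {
    C <- 1L; Z <- length(planes); T <- 1L
    bd <- if (pages[[1]]$bits == 16) 16L else 8L
    channels <- NULL
    psize <- rep(NA_real_, 3)
  } else {
    C <- as.integer(ome$sizeC); Z <- as.integer(ome$sizeZ); T <- as.integer(ome$sizeT)
    if (C * Z * T != length(planes))
      .formatError("plane count mismatch in %s: OME declares %d planes, file has %d",
                   path, C * Z * T, length(planes))
    bd <- if (!is.na(ome$significantBits)) as.integer(ome$significantBits)
          else if (identical(ome$type, "uint16")) 16L else 8L
    channels <- ome$channels
    if (length(channels) != C) channels <- NULL
    psize <- ome$physicalSize
  }
  px <- array(0L, dim = c(X, Y, C, Z, T))
  i <- 1L
  for (t in seq_len(T)) for (z in seq_len(Z)) for (c in seq_len(C)) {
    px[, , c, z, t] <- t(planes[[i]])  # C varies fastest (XYCZT plane order)
    i <- i + 1L
  }
  ImageVolume(px, bitDepth = bd, pixelSize = psize, channels = channels,
              sourceName = src)
}

#' Read a pyramidal RGB whole-slide image
#'
#' Accepts SubIFD-organized OME-TIFF pyramids (one main IFD per focal plane,
#' reduced levels as SubIFDs) and plain multi-page TIFFs whose pages form a
#' strictly shrinking level sequence (single focal plane). Levels are sorted
#' by width, base first; all focal planes must agree in level geometry.
#'
#' @param path input pyramid file.
#' @return a \linkS4class{PyramidImage}.
#' @export
readPyramid <- function(path) {
  desc <- sniffSource(path)
  if (desc@detectedKind != "pyramid")
    .formatError("not a recognized pyramid (detected %s): %s",
                 desc@detectedKind, path)
  tf <- .tiffRead(path, decode = TRUE)
  pages <- tf$pages
  asRGB <- function(p) {
    px <- p$pixels
    if (length(dim(px)) == 2L) px <- array(px, dim = c(dim(px), 1L))
    if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
    px[, , 1:3, drop = FALSE]
  }
  nsub <- length(pages[[1]]$subifds)
  if (nsub > 0L) {
    # one main IFD per z-plane, SubIFDs hold the reduced levels
    nlev <- nsub + 1L
    if (!all(vapply(pages, function(p) length(p$subifds), 1L) == nsub))
      .formatError("inconsistent z-plane level counts in %s", path)
    node_at <- function(p, li) if (li == 1L) p else p$subifds[[li - 1L]]
    ref_dims <- lapply(seq_len(nlev), function(li)
      c(node_at(pages[[1]], li)$width, node_at(pages[[1]], li)$height))
    for (p in pages) for (li in seq_len(nlev))
      if (!identical(c(node_at(p, li)$width, node_at(p, li)$height),
                     ref_dims[[li]]))
        .formatError("inconsistent level geometry across z-planes in %s", path)
    levels <- lapply(seq_len(nlev), function(li) {
      planes <- lapply(pages, function(p) asRGB(node_at(p, li)))
      PyramidLevel(planes, downsample = ref_dims[[1]][1] / ref_dims[[li]][1])
    })
  } else {
    widths <- vapply(pages, function(p) p$width, 1)
    if (length(pages) > 1L && length(unique(widths)) == 1L) {
      # equal-size main pages: focal planes of a single-level pyramid
      levels <- list(PyramidLevel(lapply(pages, asRGB), downsample = 1))
    } else {
      # pages are levels; single focal plane
      pages <- pages[order(widths, decreasing = TRUE)]
      base_w <- max(widths)
      levels <- lapply(pages, function(p)
        PyramidLevel(list(asRGB(p)), downsample = base_w / p$width))
    }
  }
  PyramidImage(levels, sourceName = basename(path))
}

#' Convert a flat tiled TIFF into a pyramidal OME-TIFF
#'
#' The fallback path for slide images whose reduced-resolution levels are
#' absent or unreadable: the base level is re-tiled and successively
#' 2x area-average downsampled until the smaller dimension is at most the
#' tile size; all levels are written as a SubIFD-organized, 512-tile,
#' JPEG-compressed OME-TIFF that \code{\link{readPyramid}} accepts.
#'
#' @param path input file (kind \code{unrecognized_pyramid}, unless forced).
#' @param jpegQuality JPEG quality for the re-encoded tiles (default 90).
#' @param out output path; default replaces the extension with
#'   \code{.ome.tiff}.
#' @param overwrite overwrite an existing output file.
#' @param force pyramidalize even when the input is already recognized.
#' @param tileSize tile edge in pixels (default 512); level generation stops
#'   once \code{min(width, height) <= tileSize}.
#' @return the output path, invisibly.
#' @export
pyramidalize <- function(path, jpegQuality = 90, out = NULL, overwrite = FALSE,
                         force = FALSE, tileSize = 512L) {
  desc <- sniffSource(path)
  if (desc@detectedKind != "unrecognized_pyramid" && !force)
    .formatError("input is already recognized as %s (use force = TRUE): %s",
                 desc@detectedKind, path)
  if (is.null(out))
    out <- paste0(tools::file_path_sans_ext(path), ".ome.tiff")
  if (file.exists(out) && !overwrite)
    stop("output exists (use overwrite = TRUE): ", out)
  tf <- tryCatch(.tiffRead(path, decode = TRUE),
                 error = function(e) .formatError("base level unreadable in %s: %s",
                                                 path, conditionMessage(e)))
  pages <- tf$pages
  base_i <- which.max(vapply(pages, function(p) p$width, 1))
  base <- pages[[base_i]]$pixels
  if (length(dim(base)) == 2L) base <- array(base, dim = c(dim(base), 1L))
  if (dim(base)[3] == 1L) base <- base[, , c(1L, 1L, 1L), drop = FALSE]
  levels <- list(base)
  while (min(dim(levels[[length(levels)]])[1:2]) > tileSize)
    levels[[length(levels) + 1L]] <- .areaHalve(levels[[length(levels)]])
  ome <- .omeBuildPyramidXML(sizeX = dim(base)[2], sizeY = dim(base)[1],
                             sizeZ = 1L, name = basename(path),
                             nLevels = length(levels),
                             jpegQuality = jpegQuality)
  mk <- function(px, first, sub) {
    list(pixels = px, bits = 8L, compression = "jpeg", quality = jpegQuality,
         tile_size = tileSize,
         description = if (first) ome else NULL,
         software = sprintf("dicomizer pyramidalize jpeg_quality=%d",
                            as.integer(jpegQuality)),
         subfiletype = if (first) 0L else 1L,
         subifds = sub)
  }
  subs <- lapply(levels[-1], function(px) mk(px, FALSE, NULL))
  .tiffWrite(out, list(mk(levels[[1]], TRUE, subs)))
  invisible(out)
}
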