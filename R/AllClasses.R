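#' @import methods
NULL

#' Acquisition metadata for one microscopy channel
#'
#' Carries the per-channel acquisition description of a confocal volume:
#' identifier, display name, illumination type, magnification and (optional)
#' emission/excitation wavelengths in nanometres. These six values are what
#' the DICOMizer later embeds verbatim in a private tag block of every
#' instance cut from that channel.
#'
#' @slot channelID   Non-empty channel identifier (text).
#' @slot channelName Human-readable channel name, e.g. \code{"DAPI"}.
#' @slot illuminationType Illumination description, e.g. \code{"Epifluorescence"}.
#' @slot magnification Magnification description, e.g. \code{"63x"}.
#' @slot emissionWavelength Emission wavelength in nm (\code{NA} if unknown).
#' @slot excitationWavelength Excitation wavelength in nm (\code{NA} if unknown).
#' @export
setClass("ChannelInfo",
  representation(
    channelID = "character",
    channelName = "character",
    illuminationType = "character",
    magnification = "character",
    emissionWavelength = "numeric",
    excitationWavelength = "numeric"
  ),
  prototype(
    channelName = "", illuminationType = "", magnification = "",
    emissionWavelength = NA_real_, excitationWavelength = NA_real_
  ),
  validity = function(object) {
    if (length(object@channelID) != 1L || is.na(object@channelID) ||
        !nzchar(object@channelID))
      return("channelID: must be a single non-empty string")
    TRUE
  }
)

#' Constructor for ChannelInfo
#' @param channelID non-empty channel identifier.
#' @param channelName display name.
#' @param illuminationType illumination description.
#' @param magnification magnification description.
#' @param emissionWavelength emission wavelength (nm) or NA.
#' @param excitationWavelength excitation wavelength (nm) or NA.
#' @return A \linkS4class{ChannelInfo} object.
#' @export
ChannelInfo <- function(channelID, channelName = "", illuminationType = "",
                        magnification = "", emissionWavelength = NA_real_,
                        excitationWavelength = NA_real_) {
  new("ChannelInfo", channelID = as.character(channelID),
      channelName = as.character(channelName),
      illuminationType = as.character(illuminationType),
      magnification = as.character(magnification),
      emissionWavelength = as.numeric(emissionWavelength),
      excitationWavelength = as.numeric(excitationWavelength))
}

#' A five-axis (XYCZT) grayscale microscopy volume
#'
#' In-memory model of a confocal (CLSM-like) multichannel z-stack or a serial
#' electron-microscopy section stack. The pixel array is always ordered
#' X, Y, C, Z, T regardless of the on-disk layout; ingestion reorders.
#' Intensities are unsigned integers; 12-bit data travels in a 16-bit
#' container with \code{bitDepth} recording the true stored depth.
#'
#' @slot pixels 5-d integer array, dimensions (X, Y, C, Z, T).
#' @slot bitDepth One of 8, 12, 16 (bits stored per pixel).
#' @slot pixelSize Numeric length-3: physical voxel width/height/depth in
#'   micrometres (\code{NA} where unknown).
#' @slot channels List of \linkS4class{ChannelInfo}, one per C-axis entry.
#' @slot sourceName Text label of the originating file.
#' @export
setClass("ImageVolume",
  representation(
    pixels = "array",
    bitDepth = "integer",
    pixelSize = "numeric",
    channels = "list",
    sourceName = "character"
  ),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 5L)
      return("pixels: must be a 5-axis array ordered X,Y,C,Z,T")
    if (any(d[3:5] < 1L))
      return("pixels: C, Z and T axis lengths must all be >= 1")
    if (!(object@bitDepth %in% c(8L, 12L, 16L)))
      return("bitDepth: must be one of 8, 12, 16")
    mx <- suppressWarnings(max(object@pixels))
    if (is.finite(mx) && mx >= 2^object@bitDepth)
      return(sprintf("pixels: maximum value %d exceeds 2^bitDepth - 1 = %d",
                     mx, 2^object@bitDepth - 1L))
    if (length(object@channels) != d[3])
      return(sprintf("channels: length %d does not match C axis length %d",
                     length(object@channels), d[3]))
    if (!all(vapply(object@channels, is, TRUE, "ChannelInfo")))
      return("channels: every element must be a ChannelInfo")
    if (length(object@pixelSize) != 3L)
      return("pixelSize: must be numeric length 3 (x, y, z in micrometres)")
    TRUE
  }
)

#' Constructor for ImageVolume
#' @param pixels 5-d integer array (X, Y, C, Z, T).
#' @param bitDepth 8, 12 or 16.
#' @param pixelSize length-3 numeric, micrometres per voxel (NA allowed).
#' @param channels list of \linkS4class{ChannelInfo}; defaults are generated
#'   when omitted.
#' @param sourceName label of the source file.
#' @return An \linkS4class{ImageVolume}.
#' @export
ImageVolume <- function(pixels, bitDepth, pixelSize = rep(NA_real_, 3),
                        channels = NULL, sourceName = "") {
  storage.mode(pixels) <- "integer"
  if (is.null(channels)) {
    nc <- if (length(dim(pixels)) >= 3L) dim(pixels)[3] else 1L
    channels <- lapply(seq_len(nc), function(i)
      ChannelInfo(channelID = sprintf("Channel:%d", i - 1L),
                  channelName = sprintf("channel-%d", i - 1L)))
  }
  new("ImageVolume", pixels = pixels, bitDepth = as.integer(bitDepth),
      pixelSize = as.numeric(pixelSize), channels = channels,
      sourceName = as.character(sourceName))
}

#' One resolution level of a whole-slide pyramid
#'
#' Holds the RGB pixel planes of a single pyramid level, one plane per focal
#' (z) depth, stored as raw arrays of dimension (height, width, 3). Region
#' access through \code{\link{getRegion}} is pure and clips/pads at edges.
#'
#' @slot width,height Level dimensions in pixels.
#' @slot downsample Base width / level width (1 for the base level).
#' @slot planes List (length = z planes) of raw arrays (h, w, 3).
#' @export
setClass("PyramidLevel",
  representation(
    width = "integer",
    height = "integer",
    downsample = "numeric",
    planes = "list"
  ),
  validity = function(object) {
    if (object@width < 1L || object@height < 1L)
      return("width/height: must be >= 1")
    if (object@downsample < 1)
      return("downsample: must be >= 1 (and 1 for the base level)")
    ok <- vapply(object@planes, function(p)
      is.raw(p) && length(dim(p)) == 3L &&
        all(dim(p) == c(object@height, object@width, 3L)), TRUE)
    if (!all(ok))
      return("planes: every plane must be a raw array of dim (height, width, 3)")
    TRUE
  }
)

#' Constructor for PyramidLevel
#' @param planes list of raw or integer arrays (h, w, 3), one per z-plane;
#'   integer input in 0..255 is packed to raw.
#' @param downsample base width divided by this level's width.
#' @return A \linkS4class{PyramidLevel}.
#' @export
PyramidLevel <- function(planes, downsample = 1) {
  planes <- lapply(planes, function(p) {
    if (!is.raw(p)) {
      d <- dim(p)
      p <- as.raw(p)
      dim(p) <- d
    }
    p
  })
  d <- dim(planes[[1]])
  new("PyramidLevel", width = as.integer(d[2]), height = as.integer(d[1]),
      downsample = as.numeric(downsample), planes = planes)
}

#' A multi-resolution RGB whole-slide image
#'
#' Ordered list of resolution levels, strictly decreasing in width, each
#' carrying the same number of focal (z) planes. The background value is the
#' RGB triple used to pad edge tiles; brightfield slides have a white
#' background, which is the default.
#'
#' @slot levels List of \linkS4class{PyramidLevel}, widths strictly decreasing.
#' @slot zPlanes Number of focal planes (>= 1), shared by all levels.
#' @slot background Integer RGB triple in 0..255 used for padding.
#' @slot sourceName Text label of the originating file.
#' @export
setClass("PyramidImage",
  representation(
    levels = "list",
    zPlanes = "integer",
    background = "integer",
    sourceName = "character"
  ),
  prototype(background = c(255L, 255L, 255L)),
  validity = function(object) {
    if (length(object@levels) == 0L)
      return("levels: must be non-empty")
    if (!all(vapply(object@levels, is, TRUE, "PyramidLevel")))
      return("levels: every element must be a PyramidLevel")
    w <- vapply(object@levels, function(l) l@width, 1L)
    if (any(diff(w) >= 0))
      return("levels: widths must be strictly decreasing")
    if (object@zPlanes < 1L)
      return("zPlanes: must be >= 1")
    nz <- vapply(object@levels, function(l) length(l@planes), 1L)
    if (!all(nz == object@zPlanes))
      return("levels: all levels must share the same z-plane count (zPlanes)")
    if (length(object@background) != 3L ||
        any(object@background < 0L | object@background > 255L))
      return("background: must be an RGB triple in 0..255")
    TRUE
  }
)

#' Constructor for PyramidImage
#' @param levels list of \linkS4class{PyramidLevel}, base level first.
#' @param background RGB padding triple, default white.
#' @param sourceName label of the source file.
#' @return A \linkS4class{PyramidImage}.
#' @export
PyramidImage <- function(levels, background = c(255L, 255L, 255L),
                         sourceName = "") {
  zp <- if (length(levels)) length(levels[[1]]@planes) else 0L
  new("PyramidImage", levels = levels, zPlanes = as.integer(zp),
      background = as.integer(background), sourceName = as.character(sourceName))
}

#' Planned output resolution levels for a pyramid conversion
#'
#' The result of gap-filling level planning: every source level contributes a
#' native entry at its own dimensions plus, unless an existing level already
#' sits there, a synthesized entry at half its dimensions. Entries are sorted
#' by output width, largest first.
#'
#' @slot entries data.frame with columns \code{source_level} (1-based index
#'   into the pyramid's levels), \code{mode} ("native" or "synthesized"),
#'   \code{out_width}, \code{out_height}.
#' @export
setClass("LevelPlan",
  representation(entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    need <- c("source_level", "mode", "out_width", "out_height")
    if (!all(need %in% names(e)))
      return(paste("entries: must have columns", paste(need, collapse = ", ")))
    if (!all(e$mode %in% c("native", "synthesized")))
      return("entries: mode must be 'native' or 'synthesized'")
    if (anyDuplicated(e[, c("out_width", "out_height")]))
      return("entries: no two entries may share (out_width, out_height)")
    if (is.unsorted(rev(e$out_width)) && any(diff(e$out_width) > 0))
      return("entries: must be sorted by out_width descending")
    if (any(e$out_width < 1L) || any(e$out_height < 1L))
      return("entries: out dimensions must be >= 1")
    TRUE
  }
)

#' The attribute set and pixel payload of one DICOM output file
#'
#' Transfer-syntax-tagged description of a single instance before it is
#' serialized to a Part 10 file: the ordered data elements, the SOP class,
#' and the pixel payload (raw bytes for the uncompressed single-frame path,
#' or a list of independently decodable JPEG streams for the encapsulated
#' multi-frame path).
#'
#' @slot attributes List of data elements; each is
#'   \code{list(group, element, vr, value)}.
#' @slot transferSyntaxUID Transfer syntax UID (dotted decimal, <= 64 chars).
#' @slot sopClassUID SOP class UID.
#' @slot pixelPayload Raw vector (native path) or list of raw vectors
#'   (encapsulated frames).
#' @slot frameCount Number of frames carried by the payload.
#' @export
setClass("DicomInstanceSpec",
  representation(
    attributes = "list",
    transferSyntaxUID = "character",
    sopClassUID = "character",
    pixelPayload = "ANY",
    frameCount = "integer"
  ),
  validity = function(object) {
    if (!isValidUID(object@sopClassUID))
      return("sopClassUID: not a syntactically valid UID (digits/dots, <= 64 chars)")
    if (!isValidUID(object@transferSyntaxUID))
      return("transferSyntaxUID: not a syntactically valid UID (digits/dots, <= 64 chars)")
    if (is.list(object@pixelPayload)) {
      if (object@frameCount != length(object@pixelPayload))
        return(sprintf(
          "frameCount: %d does not match number of encapsulated frames %d",
          object@frameCount, length(object@pixelPayload)))
    } else if (is.raw(object@pixelPayload)) {
      if (object@frameCount != 1L)
        return("frameCount: must be 1 for the raw single-frame path")
    } else return("pixelPayload: must be a raw vector or a list of raw frames")
    TRUE
  }
)

#' Content-hash derived DICOM identifier bundle
#'
#' Identifier hierarchy derived from the SHA-1 digest of the source file:
#' the patient ID is the digest rendered in decimal, the study UID prefixes
#' it with \code{"1."}, the series UID appends the series index, and the SOP
#' UID appends the instance index.
#'
#' @slot patientID Decimal text (<= 49 characters, no leading zero).
#' @slot studyUID \code{"1." + patientID}.
#' @slot seriesUID \code{studyUID + "." + series index}.
#' @slot sopUID \code{seriesUID + "." + instance index}.
#' @export
setClass("UIDSet",
  representation(
    patientID = "character",
    studyUID = "character",
    seriesUID = "character",
    sopUID = "character"
  ),
  validity = function(object) {
    for (nm in c("patientID", "studyUID", "seriesUID", "sopUID")) {
      v <- slot(object, nm)
      if (length(v) != 1L || is.na(v)) return(sprintf("%s: must be a single string", nm))
      if (nchar(v) > 64L) return(sprintf("%s: exceeds 64 characters (%d)", nm, nchar(v)))
    }
    if (!isValidUID(object@studyUID)) return("studyUID: invalid UID grammar")
    if (!isValidUID(object@seriesUID)) return("seriesUID: invalid UID grammar")
    if (!isValidUID(object@sopUID)) return("sopUID: invalid UID grammar")
    if (object@studyUID != paste0("1.", object@patientID))
      return("studyUID: must equal '1.' + patientID")
    if (!startsWith(object@seriesUID, paste0(object@studyUID, ".")))
      return("seriesUID: must extend studyUID by one component")
    if (!startsWith(object@sopUID, paste0(object@seriesUID, ".")))
      return("sopUID: must extend seriesUID by one component")
    TRUE
  }
)

#' Validate DICOM UID grammar
#'
#' A UID is a dot-separated list of decimal components, at most 64 characters,
#' where no component is empty or carries a leading zero (a lone \code{"0"}
#' is allowed).
#'
#' @param uid character vector to check.
#' @return logical vector.
#' @export
isValidUID <- function(uid) {
  vapply(uid, function(u) {
    if (is.na(u) || !nzchar(u) || nchar(u) > 64L) return(FALSE)
    grepl("^(0|[1-9][0-9]*)(\\.(0|[1-9][0-9]*))*$", u)
  }, TRUE, USE.NAMES = FALSE)
}
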