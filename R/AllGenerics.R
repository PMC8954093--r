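#' Read a rectangular RGB region from a pyramid level
#'
#' Pure accessor: repeated reads of the same region return identical pixels.
#' Regions may extend past the level edges; out-of-bounds pixels are filled
#' with \code{background}.
#'
#' @param x a \linkS4class{PyramidLevel}.
#' @param z 1-based focal plane index.
#' @param x0,y0 1-based top-left corner of the region.
#' @param w,h region width and height in pixels.
#' @param background integer RGB triple used to pad beyond the edges.
#' @return integer array (h, w, 3) with values in 0..255.
#' @export
setGeneric("getRegion", function(x, z, x0, y0, w, h,
                                 background = c(255L, 255L, 255L))
  standardGeneric("getRegion"))

#' @rdname getRegion
setMethod("getRegion", "PyramidLevel",
  function(x, z, x0, y0, w, h, background = c(255L, 255L, 255L)) {
    stopifnot(z >= 1L, z <= length(x@planes), w >= 1L, h >= 1L)
    out <- array(rep(as.integer(background), each = as.integer(h) * as.integer(w)),
                 dim = c(h, w, 3L))
    xs <- max(1L, x0); xe <- min(x@width, x0 + w - 1L)
    ys <- max(1L, y0); ye <- min(x@height, y0 + h - 1L)
    if (xs <= xe && ys <= ye) {
      sub <- x@planes[[z]][ys:ye, xs:xe, , drop = FALSE]
      sub <- array(as.integer(sub), dim = dim(sub))
      out[(ys - y0 + 1L):(ye - y0 + 1L), (xs - x0 + 1L):(xe - x0 + 1L), ] <- sub
    }
    out
  })

#' Number of channels of a volume
#' @param x an \linkS4class{ImageVolume}.
#' @return integer.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname nChannels
setMethod("nChannels", "ImageVolume", function(x) dim(x@pixels)[3])

#' Number of focal/optical-section planes
#' @param x an \linkS4class{ImageVolume} or \linkS4class{PyramidImage}.
#' @return integer.
#' @export
setGeneric("nZPlanes", function(x) standardGeneric("nZPlanes"))

#' @rdname nZPlanes
setMethod("nZPlanes", "ImageVolume", function(x) dim(x@pixels)[4])

#' @rdname nZPlanes
setMethod("nZPlanes", "PyramidImage", function(x) x@zPlanes)

#' Number of time points of a volume
#' @param x an \linkS4class{ImageVolume}.
#' @return integer.
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname nTimepoints
setMethod("nTimepoints", "ImageVolume", function(x) dim(x@pixels)[5])

#' Stored bit depth of a volume
#' @param x an \linkS4class{ImageVolume}.
#' @return integer (8, 12 or 16).
#' @export
setGeneric("bitDepth", function(x) standardGeneric("bitDepth"))

#' @rdname bitDepth
setMethod("bitDepth", "ImageVolume", function(x) x@bitDepth)

#' Channel metadata of a volume
#' @param x an \linkS4class{ImageVolume}.
#' @return list of \linkS4class{ChannelInfo}.
#' @export
setGeneric("channelInfo", function(x) standardGeneric("channelInfo"))

#' @rdname channelInfo
setMethod("channelInfo", "ImageVolume", function(x) x@channels)

#' Resolution levels of a pyramid
#' @param x a \linkS4class{PyramidImage}.
#' @return list of \linkS4class{PyramidLevel}.
#' @export
setGeneric("pyramidLevels", function(x) standardGeneric("pyramidLevels"))

#' @rdname pyramidLevels
setMethod("pyramidLevels", "PyramidImage", function(x) x@levels)

#' Widths of a pyramid's levels, base first
#' @param x a \linkS4class{PyramidImage}.
#' @return integer vector.
#' @export
setGeneric("levelWidths", function(x) standardGeneric("levelWidths"))

#' @rdname levelWidths
setMethod("levelWidths", "PyramidImage",
          function(x) vapply(x@levels, function(l) l@width, 1L))

#' Entries of a level plan
#' @param x a \linkS4class{LevelPlan}.
#' @return data.frame with columns source_level, mode, out_width, out_height.
#' @export
setGeneric("planEntries", function(x) standardGeneric("planEntries"))

#' @rdname planEntries
setMethod("planEntries", "LevelPlan", function(x) x@entries)

setMethod("show", "ChannelInfo", function(object) {
  cat(sprintf("ChannelInfo '%s' (%s)\n", object@channelID,
              ifelse(nzchar(object@channelName), object@channelName, "unnamed")))
})

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageVolume (XYCZT) %d x %d x %d x %d x %d, %d-bit\n",
              d[1], d[2], d[3], d[4], d[5], object@bitDepth))
  if (nzchar(object@sourceName))
    cat("  source:", object@sourceName, "\n")
})

setMethod("show", "PyramidImage", function(object) {
  cat(sprintf("PyramidImage: %d level(s), %d z-plane(s)\n",
              length(object@levels), object@zPlanes))
  for (i in seq_along(object@levels)) {
    l <- object@levels[[i]]
    cat(sprintf("  level %d: %d x %d (downsample %.6g)\n",
                i - 1L, l@width, l@height, l@downsample))
  }
})

setMethod("show", "LevelPlan", function(object) {
  cat(sprintf("LevelPlan with %d entries\n", nrow(object@entries)))
  print(object@entries, row.names = FALSE)
})

setMethod("show", "DicomInstanceSpec", function(object) {
  cat(sprintf("DicomInstanceSpec: SOP class %s, transfer syntax %s, %d frame(s)\n",
              object@sopClassUID, object@transferSyntaxUID, object@frameCount))
})

setMethod("show", "UIDSet", function(object) {
  cat("UIDSet\n",
      " patient:", object@patientID, "\n",
      " study:  ", object@studyUID, "\n",
      " series: ", object@seriesUID, "\n",
      " sop:    ", object@sopUID, "\n")
})
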