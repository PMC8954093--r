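# Volume pathway: one single-frame VL Microscopic Image Storage instance per
# (channel, z, t) slice, explicit VR little-endian, uncompressed pixel data.

#' Plan the instances of a volume conversion
#'
#' Enumerates one output instance per (channel, z, t) slice, channel-major
#' (channel slowest, then z, then t), with sequential 0-based instance
#' indices. A C-channel, Z-plane, T-point volume always yields C*Z*T
#' instances.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @return data.frame with 0-based columns \code{channel}, \code{z}, \code{t}
#'   and \code{instance}.
#' @export
planInstances <- function(volume) {
  stopifnot(is(volume, "ImageVolume"))
  d <- dim(volume@pixels)
  grid <- expand.grid(t = seq_len(d[5]) - 1L, z = seq_len(d[4]) - 1L,
                      channel = seq_len(d[3]) - 1L)
  grid <- grid[order(grid$channel, grid$z, grid$t), c("channel", "z", "t")]
  grid$instance <- seq_len(nrow(grid)) - 1L
  rownames(grid) <- NULL
  grid
}

#' Build one single-frame DICOM instance from a volume slice
#'
#' Emits the VL Microscopic Image Storage SOP class under the explicit VR
#' little-endian transfer syntax: MONOCHROME2, one sample per pixel,
#' (Bits Allocated, Bits Stored, High Bit) of (8,8,7), (16,12,11) or
#' (16,16,15) according to the stored bit depth, and the raw slice as
#' little-endian pixel data.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param channelIdx,zIdx,tIdx 0-based slice indices.
#' @param uids a \linkS4class{UIDSet} for this instance.
#' @param instanceNumber 1-based Instance Number attribute value; defaults to
#'   the 0-based instance index + 1 implied by the UID's last component.
#' @return a \linkS4class{DicomInstanceSpec}.
#' @export
buildInstance <- function(volume, channelIdx, zIdx, tIdx, uids,
                          instanceNumber = NULL) {
  stopifnot(is(volume, "ImageVolume"), is(uids, "UIDSet"))
  d <- dim(volume@pixels)
  if (channelIdx < 0L || channelIdx >= d[3] || zIdx < 0L || zIdx >= d[4] ||
      tIdx < 0L || tIdx >= d[5])
    stop(sprintf("slice indices (c=%d, z=%d, t=%d) outside volume axes %d x %d x %d",
                 channelIdx, zIdx, tIdx, d[3], d[4], d[5]))
  bd <- volume@bitDepth
  bits <- switch(as.character(bd),
    "8" = c(8L, 8L, 7L), "12" = c(16L, 12L, 11L), "16" = c(16L, 16L, 15L),
    stop("unsupported bit depth ", bd, " (must be 8, 12 or 16)"))
  if (is.null(instanceNumber)) {
    parts <- strsplit(uids@sopUID, ".", fixed = TRUE)[[1]]
    instanceNumber <- as.integer(parts[length(parts)]) + 1L
  }
  slice <- volume@pixels[, , channelIdx + 1L, zIdx + 1L, tIdx + 1L]
  v <- as.integer(slice)  # x fastest within each row: row-major raster
  payload <- if (bits[1] == 8L) as.raw(v) else .u16le(v)
  attr(payload, "vr") <- if (bits[1] == 8L) "OB" else "OW"
  attrs <- c(
    .dcmIdentityAttrs(uids, .UID_VL_MICROSCOPIC, "GM",
                      instance_number = instanceNumber),
    list(
      .attr(0x0008, 0x0008, "CS", c("ORIGINAL", "PRIMARY")),
      .attr(0x0028, 0x0002, "US", 1L),
      .attr(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .attr(0x0028, 0x0010, "US", d[2]),   # Rows    = Y
      .attr(0x0028, 0x0011, "US", d[1]),   # Columns = X
      .attr(0x0028, 0x0100, "US", bits[1]),
      .attr(0x0028, 0x0101, "US", bits[2]),
      .attr(0x0028, 0x0102, "US", bits[3]),
      .attr(0x0028, 0x0103, "US", 0L)
    ))
  new("DicomInstanceSpec", attributes = attrs,
      transferSyntaxUID = .UID_EXPLICIT_VR_LE,
      sopClassUID = .UID_VL_MICROSCOPIC,
      pixelPayload = payload, frameCount = 1L)
}

.PRIVATE_GROUP <- 0x0011
.PRIVATE_CREATOR <- "DICOMIZER MICROSCOPY"

#' Embed microscope acquisition metadata as private tags
#'
#' Adds a single private block (group 0011, private creator recorded at
#' (0011,0010)) carrying six text values: channel name, dimension order
#' ("XYCZT"), illumination type, physical pixel size with units, channel ID
#' and magnification. Absent metadata is written as an empty value; a parser
#' reading the file back recovers all six verbatim.
#'
#' @param spec a \linkS4class{DicomInstanceSpec} from \code{\link{buildInstance}}.
#' @param channel a \linkS4class{ChannelInfo}.
#' @param pixelSize numeric length-3 voxel size in micrometres (NA allowed).
#' @return the spec with the private block appended.
#' @export
embedPrivateTags <- function(spec, channel, pixelSize = rep(NA_real_, 3)) {
  stopifnot(is(spec, "DicomInstanceSpec"), is(channel, "ChannelInfo"))
  psz <- if (all(is.na(pixelSize))) "" else
    paste0(paste(signif(pixelSize[!is.na(pixelSize)], 6), collapse = "x"), " um")
  block <- list(
    .attr(.PRIVATE_GROUP, 0x0010, "LO", .PRIVATE_CREATOR),
    .attr(.PRIVATE_GROUP, 0x1001, "LO", channel@channelName),
    .attr(.PRIVATE_GROUP, 0x1002, "LO", "XYCZT"),
    .attr(.PRIVATE_GROUP, 0x1003, "LO", channel@illuminationType),
    .attr(.PRIVATE_GROUP, 0x1004, "LO", psz),
    .attr(.PRIVATE_GROUP, 0x1005, "LO", channel@channelID),
    .attr(.PRIVATE_GROUP, 0x1006, "LO", channel@magnification)
  )
  spec@attributes <- c(spec@attributes, block)
  spec
}

#' Convert a volume file to a DICOM series
#'
#' Full volume pathway: ingest, derive content-hash identifiers, emit one
#' Part 10 file per (channel, z, t) slice. All instances share the study and
#' series UID (series index 0); SOP instance UIDs are sequential. Partial
#' output is removed if any step fails.
#'
#' @param path input volume (OME-TIFF, plain TIFF stack, MRC, PNG directory).
#' @param outDir output directory (created if missing).
#' @return (invisibly) the conversion manifest: a list with the source,
#'   identifiers and a per-file table; also written as
#'   \code{manifest.json} inside \code{outDir}.
#' @export
convertVolume <- function(path, outDir) {
  volume <- readVolume(path)
  patient <- derivePatientID(path)
  plan <- planInstances(volume)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written))
  files <- character(nrow(plan))
  sops <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    uids <- deriveUIDs(patient, 0L, p$instance)
    spec <- buildInstance(volume, p$channel, p$z, p$t, uids,
                          instanceNumber = p$instance + 1L)
    spec <- embedPrivateTags(spec, volume@channels[[p$channel + 1L]],
                             volume@pixelSize)
    f <- file.path(outDir, sprintf("c%02d_z%04d_t%02d.dcm", p$channel, p$z, p$t))
    writeDicomInstance(spec, f)
    written <- c(written, f)
    files[i] <- basename(f)
    sops[i] <- uids@sopUID
  }
  manifest <- list(
    source = basename(if (dir.exists(path)) path else path),
    kind = "volume",
    patientID = patient,
    studyUID = paste0("1.", patient),
    seriesUID = paste0("1.", patient, ".0"),
    files = data.frame(file = files, channel = plan$channel, z = plan$z,
                       t = plan$t, sopUID = sops, stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
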