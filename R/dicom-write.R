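# DICOM Part 10 serialization: explicit VR little-endian datasets, file meta
# group, and encapsulated (JPEG baseline) multi-frame pixel data with a basic
# offset table. Only the two transfer syntaxes the converters emit are
# supported; both are written with explicit VR element structure.

.UID_VL_MICROSCOPIC <- "1.2.840.10008.5.1.4.1.1.77.1.2"
.UID_VL_WSI <- "1.2.840.10008.5.1.4.1.1.77.1.6"
.UID_EXPLICIT_VR_LE <- "1.2.840.10008.1.2.1"
.UID_JPEG_BASELINE <- "1.2.840.10008.1.2.4.50"
# UUID-derived implementation class UID (2.25 arm needs no registered root)
.UID_IMPLEMENTATION <- "2.25.313880857161271055826237818382"

.VR_LONG <- c("OB", "OW", "OF", "SQ", "UT", "UN")
.VR_TEXT <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
              "SH", "ST", "TM", "UI", "UT")

# encode one data element (explicit VR little-endian)
#' @noRd
.dcmElement <- function(group, element, vr, value) {
  bytes <- if (vr %in% .VR_TEXT) {
    s <- paste(as.character(value), collapse = "\\")
    b <- charToRaw(s)
    if (length(b) %% 2L == 1L)
      b <- c(b, if (vr == "UI") as.raw(0L) else charToRaw(" "))
    b
  } else if (vr == "US") {
    .u16le(as.integer(value))
  } else if (vr == "UL") {
    .u32le(value)
  } else if (vr %in% c("OB", "OW", "UN")) {
    b <- as.raw(value)
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else stop("unsupported VR for writing: ", vr)
  hdr <- c(.u16le(group), .u16le(element), charToRaw(vr))
  if (vr %in% .VR_LONG) {
    c(hdr, raw(2), .u32le(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534L)
      stop(sprintf("value too long for short-form VR %s at (%04X,%04X)",
                   vr, group, element))
    c(hdr, .u16le(length(bytes)), bytes)
  }
}

# encapsulated pixel data element: undefined length OB, basic offset table
# item, one item per frame, sequence delimitation item
#' @noRd
.dcmEncapsulatedPixelData <- function(frames) {
  pad <- function(b) if (length(b) %% 2L == 1L) c(b, as.raw(0L)) else b
  frames <- lapply(frames, pad)
  sizes <- vapply(frames, length, 1)
  # offset of each frame's item header from the byte after the BOT item
  offsets <- cumsum(c(0, head(sizes + 8, -1)))
  item <- function(payload) c(.u16le(c(0xFFFE, 0xE000)), .u32le(length(payload)), payload)
  bot <- item(.u32le(offsets))
  body <- c(bot, unlist(lapply(frames, item)),
            .u16le(c(0xFFFE, 0xE0DD)), .u32le(0))
  c(.u16le(c(0x7FE0, 0x0010)), charToRaw("OB"), raw(2),
    as.raw(c(0xFF, 0xFF, 0xFF, 0xFF)), body)
}

#' @noRd
.dcmFileMeta <- function(sop_class, sop_instance, transfer_syntax) {
  body <- c(
    .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0x00, 0x01))),
    .dcmElement(0x0002, 0x0002, "UI", sop_class),
    .dcmElement(0x0002, 0x0003, "UI", sop_instance),
    .dcmElement(0x0002, 0x0010, "UI", transfer_syntax),
    .dcmElement(0x0002, 0x0012, "UI", .UID_IMPLEMENTATION)
  )
  c(.dcmElement(0x0002, 0x0000, "UL", length(body)), body)
}

#' Serialize a DicomInstanceSpec to a Part 10 file
#'
#' Writes the 128-byte preamble, "DICM" magic, the file meta group (explicit
#' VR little-endian) and the dataset. Uncompressed payloads are written as a
#' native OB/OW PixelData element; compressed payloads are encapsulated with
#' a basic offset table.
#'
#' @param spec a \linkS4class{DicomInstanceSpec}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeDicomInstance <- function(spec, path) {
  stopifnot(is(spec, "DicomInstanceSpec"))
  sop_instance <- NULL
  for (a in spec@attributes)
    if (a$group == 0x0008 && a$element == 0x0018) sop_instance <- a$value
  if (is.null(sop_instance))
    stop("spec has no SOP Instance UID attribute (0008,0018)")
  ord <- order(vapply(spec@attributes, function(a) a$group * 2^16 + a$element, 1))
  ds <- unlist(lapply(spec@attributes[ord], function(a)
    .dcmElement(a$group, a$element, a$vr, a$value)))
  px <- if (is.list(spec@pixelPayload)) {
    .dcmEncapsulatedPixelData(spec@pixelPayload)
  } else {
    vr <- attr(spec@pixelPayload, "vr")
    if (is.null(vr)) vr <- "OB"
    .dcmElement(0x7FE0, 0x0010, vr, spec@pixelPayload)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(.dcmFileMeta(spec@sopClassUID, sop_instance, spec@transferSyntaxUID), con)
  writeBin(c(ds, px), con)
  invisible(path)
}

# helper used by both dicomizers to assemble attribute lists
#' @noRd
.attr <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

# shared patient/study/series/instance identity attributes
#' @noRd
.dcmIdentityAttrs <- function(uids, sop_class, modality, instance_number,
                              patient_name = "microscopy^sample") {
  parts <- strsplit(uids@seriesUID, ".", fixed = TRUE)[[1]]
  series_number <- parts[length(parts)]
  list(
    .attr(0x0008, 0x0016, "UI", sop_class),
    .attr(0x0008, 0x0018, "UI", uids@sopUID),
    .attr(0x0008, 0x0060, "CS", modality),
    .attr(0x0010, 0x0010, "PN", patient_name),
    .attr(0x0010, 0x0020, "LO", uids@patientID),
    .attr(0x0020, 0x000D, "UI", uids@studyUID),
    .attr(0x0020, 0x000E, "UI", uids@seriesUID),
    .attr(0x0020, 0x0010, "SH", "1"),
    .attr(0x0020, 0x0011, "IS", series_number),
    .attr(0x0020, 0x0013, "IS", as.character(instance_number))
  )
}
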