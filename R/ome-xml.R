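# Minimal OME-XML construction and parsing (ImageDescription payload of
# OME-TIFF). Covers what the converters need: pixel geometry (SizeX/Y/C/Z/T),
# dimension order, pixel type and significant bits, physical voxel size, and
# per-channel acquisition metadata. Everything else in the schema is ignored.

.OME_NS <- "http://www.openmicroscopy.org/Schemas/OME/2016-06"

#' @noRd
.omeBuildVolumeXML <- function(sizeX, sizeY, sizeC, sizeZ, sizeT,
                               type = "uint16", significantBits = NA,
                               physicalSize = rep(NA_real_, 3),
                               channels = list(), name = "volume") {
  doc <- xml2::xml_new_root("OME", xmlns = .OME_NS)
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0", Name = name)
  att <- list(ID = "Pixels:0", DimensionOrder = "XYCZT", Type = type,
              SizeX = sizeX, SizeY = sizeY, SizeC = sizeC,
              SizeZ = sizeZ, SizeT = sizeT)
  if (!is.na(significantBits)) att$SignificantBits <- significantBits
  if (!is.na(physicalSize[1])) {
    att$PhysicalSizeX <- physicalSize[1]
    att$PhysicalSizeXUnit <- "um"
  }
  if (!is.na(physicalSize[2])) {
    att$PhysicalSizeY <- physicalSize[2]
    att$PhysicalSizeYUnit <- "um"
  }
  if (!is.na(physicalSize[3])) {
    att$PhysicalSizeZ <- physicalSize[3]
    att$PhysicalSizeZUnit <- "um"
  }
  px <- xml2::xml_add_child(img, "Pixels")
  do.call(xml2::xml_set_attrs, c(list(px), list(unlist(lapply(att, as.character)))))
  for (ch in channels) {
    catt <- list(ID = ch@channelID)
    if (nzchar(ch@channelName)) catt$Name <- ch@channelName
    if (nzchar(ch@illuminationType)) catt$IlluminationType <- ch@illuminationType
    if (nzchar(ch@magnification)) catt$Magnification <- ch@magnification
    if (!is.na(ch@emissionWavelength)) catt$EmissionWavelength <- ch@emissionWavelength
    if (!is.na(ch@excitationWavelength)) catt$ExcitationWavelength <- ch@excitationWavelength
    nd <- xml2::xml_add_child(px, "Channel")
    do.call(xml2::xml_set_attrs, c(list(nd), list(unlist(lapply(catt, as.character)))))
  }
  xml2::xml_add_child(px, "TiffData")
  as.character(doc)
}

#' @noRd
.omeBuildPyramidXML <- function(sizeX, sizeY, sizeZ, name = "slide",
                                nLevels = 1L, jpegQuality = NA) {
  doc <- xml2::xml_new_root("OME", xmlns = .OME_NS)
  img <- xml2::xml_add_child(doc, "Image", ID = "Image:0", Name = name)
  px <- xml2::xml_add_child(img, "Pixels", ID = "Pixels:0",
                            DimensionOrder = "XYCZT", Type = "uint8",
                            Interleaved = "true",
                            SizeX = as.character(sizeX),
                            SizeY = as.character(sizeY), SizeC = "3",
                            SizeZ = as.character(sizeZ), SizeT = "1")
  xml2::xml_add_child(px, "Channel", ID = "Channel:0:0", SamplesPerPixel = "3")
  xml2::xml_add_child(px, "TiffData")
  if (!is.na(jpegQuality)) {
    sa <- xml2::xml_add_child(doc, "StructuredAnnotations")
    xa <- xml2::xml_add_child(sa, "XMLAnnotation", ID = "Annotation:0",
                              Namespace = "dicomizer.org/pyramidalize")
    val <- xml2::xml_add_child(xa, "Value")
    q <- xml2::xml_add_child(val, "JPEGQuality")
    xml2::xml_set_text(q, as.character(jpegQuality))
  }
  as.character(doc)
}

# Parse an OME-XML string; returns NULL when the text is not OME-XML.
#' @noRd
.omeParse <- function(text) {
  if (is.null(text) || !grepl("<OME", text, fixed = TRUE)) return(NULL)
  doc <- tryCatch(xml2::read_xml(text), error = function(e) NULL)
  if (is.null(doc)) return(NULL)
  xml2::xml_ns_strip(doc)
  px <- xml2::xml_find_first(doc, ".//Pixels")
  if (inherits(px, "xml_missing")) return(NULL)
  gi <- function(a, default = NA) {
    v <- xml2::xml_attr(px, a)
    if (is.na(v)) default else as.numeric(v)
  }
  channels <- lapply(xml2::xml_find_all(px, ".//Channel"), function(ch) {
    ga <- function(a) { v <- xml2::xml_attr(ch, a); if (is.na(v)) "" else v }
    gn <- function(a) { v <- xml2::xml_attr(ch, a); if (is.na(v)) NA_real_ else as.numeric(v) }
    id <- ga("ID")
    ChannelInfo(channelID = if (nzchar(id)) id else "Channel:0",
                channelName = ga("Name"),
                illuminationType = ga("IlluminationType"),
                magnification = ga("Magnification"),
                emissionWavelength = gn("EmissionWavelength"),
                excitationWavelength = gn("ExcitationWavelength"))
  })
  qnode <- xml2::xml_find_first(doc, ".//JPEGQuality")
  list(
    sizeX = gi("SizeX"), sizeY = gi("SizeY"), sizeC = gi("SizeC", 1),
    sizeZ = gi("SizeZ", 1), sizeT = gi("SizeT", 1),
    dimensionOrder = xml2::xml_attr(px, "DimensionOrder"),
    type = xml2::xml_attr(px, "Type"),
    significantBits = gi("SignificantBits"),
    physicalSize = c(gi("PhysicalSizeX"), gi("PhysicalSizeY"), gi("PhysicalSizeZ")),
    channels = channels,
    jpegQuality = if (inherits(qnode, "xml_missing")) NA_real_
                  else as.numeric(xml2::xml_text(qnode))
  )
}
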