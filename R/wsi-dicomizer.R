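# Whole-slide pathway: gap-filling level planning (every stored level is
# emitted as-is and, unless a stored level already sits there, once more at
# half its dimensions), 512x512 tiling with background padding, baseline
# JPEG encapsulation, one multi-frame VL Whole Slide Microscopy instance per
# (focal plane, planned level).

#' Plan output resolution levels, synthesizing gap fillers
#'
#' For every source level the plan holds a native entry at the level's own
#' dimensions plus a synthesized candidate at floor(dims / 2). A candidate is
#' dropped iff an existing native level matches it within one pixel on both
#' axes (floor-division off-by-one tolerance); remaining exact dimension
#' duplicates are dropped keeping the first. Entries are sorted by output
#' width, largest first. A pyramid whose adjacent levels differ 2x per axis
#' therefore gains only one deepest half-level; a 4x-spaced pyramid doubles
#' its level count.
#'
#' @param pyramid a \linkS4class{PyramidImage}.
#' @param tileSize unused in planning (kept for interface symmetry).
#' @return a \linkS4class{LevelPlan}.
#' @export
planLevels <- function(pyramid, tileSize = 512L) {
  stopifnot(is(pyramid, "PyramidImage"))
  lv <- pyramid@levels
  new("LevelPlan",
      entries = .planLevelDims(vapply(lv, function(l) l@width, 1L),
                               vapply(lv, function(l) l@height, 1L)))
}

# planning core on bare dimension lists (widths strictly decreasing)
#' @noRd
.planLevelDims <- function(nat_w, nat_h) {
  rows <- list()
  for (i in seq_along(nat_w)) {
    rows[[length(rows) + 1L]] <- data.frame(
      source_level = i, mode = "native",
      out_width = nat_w[i], out_height = nat_h[i], stringsAsFactors = FALSE)
    sw <- nat_w[i] %/% 2L; sh <- nat_h[i] %/% 2L
    if (sw >= 1L && sh >= 1L) {
      collides <- any(abs(nat_w - sw) <= 1L & abs(nat_h - sh) <= 1L)
      if (!collides)
        rows[[length(rows) + 1L]] <- data.frame(
          source_level = i, mode = "synthesized",
          out_width = sw, out_height = sh, stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, rows)
  entries <- entries[!duplicated(entries[, c("out_width", "out_height")]), ]
  entries <- entries[order(-entries$out_width, -entries$out_height), ]
  rownames(entries) <- NULL
  entries
}

#' Cut one output level into 512x512 tiles
#'
#' Native mode reads each tile directly from the source level; synthesized
#' mode reads the corresponding double-size (1024x1024) source region and
#' area-downsamples it by two. Edge tiles are padded with the background
#' value. Tiles are returned in row-major order (left-to-right, then
#' top-to-bottom), \code{ceil(outWidth/tileSize) * ceil(outHeight/tileSize)}
#' of them, each exactly tileSize x tileSize x 3.
#'
#' @param accessor function \code{(x0, y0, w, h)} returning an integer RGB
#'   region of the SOURCE level, padding beyond its edges (see
#'   \code{\link{getRegion}}).
#' @param outWidth,outHeight dimensions of the output level.
#' @param mode \code{"native"} or \code{"synthesized"}.
#' @param tileSize tile edge in pixels.
#' @param background integer RGB triple used by synthesized-mode averaging at
#'   the edges (must match the accessor's padding).
#' @return list of integer arrays (tileSize, tileSize, 3).
#' @export
tileLevel <- function(accessor, outWidth, outHeight, mode = c("native", "synthesized"),
                      tileSize = 512L, background = c(255L, 255L, 255L)) {
  mode <- match.arg(mode)
  cols <- ceiling(outWidth / tileSize)
  rows <- ceiling(outHeight / tileSize)
  tiles <- vector("list", cols * rows)
  k <- 1L
  for (ty in seq_len(rows)) {
    for (tx in seq_len(cols)) {
      tiles[[k]] <- tryCatch({
        if (mode == "native") {
          accessor((tx - 1L) * tileSize + 1L, (ty - 1L) * tileSize + 1L,
                   tileSize, tileSize)
        } else {
          src <- accessor((tx - 1L) * 2L * tileSize + 1L,
                          (ty - 1L) * 2L * tileSize + 1L,
                          2L * tileSize, 2L * tileSize)
          .areaHalve(src)
        }
      }, error = function(e)
        stop(sprintf("tile (%d, %d) of level %d x %d: %s", tx, ty,
                     outWidth, outHeight, conditionMessage(e)), call. = FALSE))
      k <- k + 1L
    }
  }
  tiles
}

#' Encode tiles as baseline JPEG frames
#'
#' One 8-bit YCbCr baseline JPEG byte stream per tile, order preserved; each
#' frame decodes independently back to tileSize x tileSize RGB.
#'
#' @param tiles list of integer arrays (h, w, 3) in 0..255.
#' @param jpegQuality quality in 1..100 (default 90).
#' @return list of raw vectors.
#' @export
encodeFrames <- function(tiles, jpegQuality = 90) {
  lapply(seq_along(tiles), function(i)
    tryCatch(jpeg::writeJPEG(tiles[[i]] / 255, raw(), quality = jpegQuality / 100),
             error = function(e)
               stop(sprintf("JPEG encoding failed for tile %d: %s", i,
                            conditionMessage(e)), call. = FALSE)))
}

#' Build one multi-frame WSI DICOM instance
#'
#' VL Whole Slide Microscopy Image Storage under the JPEG baseline transfer
#' syntax: YBR_FULL_422, three samples per pixel, Rows = Columns = tile size,
#' full row-major tiling (TILED_FULL), total pixel matrix carrying the
#' planned level dimensions, and optional device private tags.
#'
#' @param entry one row of a \linkS4class{LevelPlan}'s entries (list or
#'   single-row data.frame with out_width/out_height).
#' @param frames encapsulated frame list from \code{\link{encodeFrames}}.
#' @param uids a \linkS4class{UIDSet}.
#' @param pyramidMeta optional list with \code{deviceMaker},
#'   \code{captureMode}, \code{deviceModel} text entries.
#' @param tileSize tile edge (frame Rows/Columns).
#' @param instanceNumber 1-based Instance Number.
#' @return a \linkS4class{DicomInstanceSpec}.
#' @export
buildWsiInstance <- function(entry, frames, uids, pyramidMeta = list(),
                             tileSize = 512L, instanceNumber = 1L) {
  ow <- as.integer(entry$out_width); oh <- as.integer(entry$out_height)
  expected <- ceiling(ow / tileSize) * ceiling(oh / tileSize)
  if (length(frames) != expected)
    stop(sprintf("frame count %d inconsistent with %d x %d tile grid (%d expected)",
                 length(frames), ow, oh, expected))
  attrs <- c(
    .dcmIdentityAttrs(uids, .UID_VL_WSI, "SM", instance_number = instanceNumber),
    list(
      .attr(0x0008, 0x0008, "CS", c("ORIGINAL", "PRIMARY", "VOLUME", "NONE")),
      .attr(0x0020, 0x9311, "CS", "TILED_FULL"),
      .attr(0x0028, 0x0002, "US", 3L),
      .attr(0x0028, 0x0004, "CS", "YBR_FULL_422"),
      .attr(0x0028, 0x0006, "US", 0L),
      .attr(0x0028, 0x0008, "IS", as.character(length(frames))),
      .attr(0x0028, 0x0010, "US", tileSize),
      .attr(0x0028, 0x0011, "US", tileSize),
      .attr(0x0028, 0x0100, "US", 8L),
      .attr(0x0028, 0x0101, "US", 8L),
      .attr(0x0028, 0x0102, "US", 7L),
      .attr(0x0028, 0x0103, "US", 0L),
      .attr(0x0048, 0x0006, "UL", ow),
      .attr(0x0048, 0x0007, "UL", oh)
    ))
  gv <- function(nm) if (is.null(pyramidMeta[[nm]])) "" else pyramidMeta[[nm]]
  if (any(nzchar(c(gv("deviceMaker"), gv("captureMode"), gv("deviceModel"))))) {
    attrs <- c(attrs, list(
      .attr(.PRIVATE_GROUP, 0x0010, "LO", .PRIVATE_CREATOR),
      .attr(.PRIVATE_GROUP, 0x1011, "LO", gv("deviceMaker")),
      .attr(.PRIVATE_GROUP, 0x1012, "LO", gv("captureMode")),
      .attr(.PRIVATE_GROUP, 0x1013, "LO", gv("deviceModel"))
    ))
  }
  new("DicomInstanceSpec", attributes = attrs,
      transferSyntaxUID = .UID_JPEG_BASELINE, sopClassUID = .UID_VL_WSI,
      pixelPayload = frames, frameCount = length(frames))
}

#' Convert a pyramidal slide to tiled multi-frame DICOM series
#'
#' Full whole-slide pathway: ingest, derive content-hash identifiers, plan
#' levels with gap synthesis, then emit one output folder per focal plane
#' (series index = z index, folders \code{stack_00 ...}) holding one
#' multi-frame file per planned level (\code{level_00.dcm} = largest). The
#' study UID is shared across the conversion. Partial output is removed on
#' failure.
#'
#' @param path input pyramid file.
#' @param outDir output directory (created if missing).
#' @param tileSize tile edge in pixels (default 512).
#' @param jpegQuality JPEG quality for frame encoding (default 90).
#' @param pyramidMeta optional device metadata, see
#'   \code{\link{buildWsiInstance}}.
#' @return (invisibly) the conversion manifest (also written as
#'   \code{manifest.json} in \code{outDir}): folders, files, level
#'   dimensions and frame counts.
#' @export
convertWsi <- function(path, outDir, tileSize = 512L, jpegQuality = 90,
                       pyramidMeta = list()) {
  pyr <- readPyramid(path)
  patient <- derivePatientID(path)
  plan <- planLevels(pyr, tileSize)
  entries <- plan@entries
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written, recursive = TRUE))
  folders <- list()
  for (z in seq_len(pyr@zPlanes)) {
    folder <- sprintf("stack_%02d", z - 1L)
    fdir <- file.path(outDir, folder)
    dir.create(fdir, showWarnings = FALSE)
    written <- c(written, fdir)
    files <- list()
    for (i in seq_len(nrow(entries))) {
      e <- entries[i, ]
      lvl <- pyr@levels[[e$source_level]]
      acc <- function(x0, y0, w, h)
        getRegion(lvl, z, x0, y0, w, h, background = pyr@background)
      tiles <- tileLevel(acc, e$out_width, e$out_height, e$mode,
                         tileSize = tileSize, background = pyr@background)
      frames <- encodeFrames(tiles, jpegQuality = jpegQuality)
      uids <- deriveUIDs(patient, z - 1L, i - 1L)
      spec <- buildWsiInstance(e, frames, uids, pyramidMeta = pyramidMeta,
                               tileSize = tileSize, instanceNumber = i)
      f <- file.path(fdir, sprintf("level_%02d.dcm", i - 1L))
      writeDicomInstance(spec, f)
      files[[length(files) + 1L]] <- list(
        file = basename(f), mode = e$mode, width = e$out_width,
        height = e$out_height, frames = length(frames), sopUID = uids@sopUID)
    }
    folders[[folder]] <- list(seriesUID = paste0("1.", patient, ".", z - 1L),
                              files = files)
  }
  manifest <- list(
    source = basename(path), kind = "wsi", patientID = patient,
    studyUID = paste0("1.", patient),
    tileSize = tileSize, jpegQuality = jpegQuality,
    levels = entries, folders = folders
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}
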