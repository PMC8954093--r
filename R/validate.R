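# Read-back validation of a conversion's output directory: every Part 10
# file must parse, carry grammatically valid UIDs, have a frame count that
# matches its tile-grid arithmetic, and decode; across the conversion there
# must be a single study, one series per folder, and pairwise distinct SOP
# instance UIDs.

#' Validate a directory of converted DICOM files
#'
#' @param dicomDir directory containing Part 10 files (searched recursively;
#'   one conversion per call).
#' @param decodeFrames decode every encapsulated JPEG frame (default TRUE;
#'   set FALSE to only check frame counts and native payload sizes).
#' @return a list with \code{ok} (logical), \code{nFiles}, and
#'   \code{failures} (data.frame with columns file, check, message).
#' @export
validateDicom <- function(dicomDir, decodeFrames = TRUE) {
  if (!dir.exists(dicomDir)) stop("cannot read directory: ", dicomDir)
  files <- list.files(dicomDir, pattern = "\\.dcm$", recursive = TRUE,
                      full.names = TRUE)
  fails <- list()
  note <- function(file, check, message)
    fails[[length(fails) + 1L]] <<- data.frame(
      file = file, check = check, message = message, stringsAsFactors = FALSE)
  per_file <- list()
  for (f in files) {
    parsed <- tryCatch(readDicomInstance(f), error = function(e) e)
    if (inherits(parsed, "error")) {
      note(f, "parseable", conditionMessage(parsed))
      next
    }
    study <- .dsVal(parsed, "0020,000D")
    series <- .dsVal(parsed, "0020,000E")
    sop <- .dsVal(parsed, "0008,0018")
    uids <- list(study = study, series = series, sop = sop)
    for (nm in names(uids)) {
      v <- uids[[nm]]
      if (is.null(v) || is.na(v) || !isValidUID(v))
        note(f, "uid-grammar", sprintf("%s UID invalid: %s", nm,
                                       if (is.null(v)) "<absent>" else v))
    }
    rows <- .dsVal(parsed, "0028,0010"); cols <- .dsVal(parsed, "0028,0011")
    if (!is.null(parsed$frames)) {
      nf <- as.integer(.dsVal(parsed, "0028,0008"))
      tw <- .dsVal(parsed, "0048,0006"); th <- .dsVal(parsed, "0048,0007")
      if (length(parsed$frames) != nf)
        note(f, "frame-count", sprintf("declared %d frames, found %d",
                                       nf, length(parsed$frames)))
      if (!is.null(tw) && !is.null(th)) {
        grid <- ceiling(tw / cols) * ceiling(th / rows)
        if (nf != grid)
          note(f, "frame-grid", sprintf(
            "NumberOfFrames %d != ceil(%d/%d)*ceil(%d/%d) = %d",
            nf, tw, cols, th, rows, grid))
      }
      if (decodeFrames) {
        for (i in seq_along(parsed$frames)) {
          dec <- tryCatch(jpeg::readJPEG(parsed$frames[[i]]),
                          error = function(e) e)
          if (inherits(dec, "error")) {
            note(f, "frame-decode", sprintf("frame %d: %s", i,
                                            conditionMessage(dec)))
            break
          }
          if (!all(dim(dec)[1:2] == c(rows, cols))) {
            note(f, "frame-decode", sprintf(
              "frame %d decodes to %d x %d, expected %d x %d",
              i, dim(dec)[1], dim(dec)[2], rows, cols))
            break
          }
        }
      }
    } else if (!is.null(parsed$pixelData)) {
      ba <- .dsVal(parsed, "0028,0100")
      spp <- .dsVal(parsed, "0028,0002")
      expected <- rows * cols * (ba / 8) * spp
      got <- length(parsed$pixelData)
      if (got < expected || got > expected + 1)
        note(f, "pixel-size", sprintf("pixel data %d bytes, expected %.0f",
                                      got, expected))
    } else {
      note(f, "pixel-data", "no pixel data element")
    }
    per_file[[f]] <- list(study = study, series = series, sop = sop)
  }
  if (length(per_file)) {
    studies <- unique(vapply(per_file, function(x) as.character(x$study), ""))
    if (length(studies) != 1L)
      note("<conversion>", "single-study",
           sprintf("found %d distinct study UIDs", length(studies)))
    sops <- vapply(per_file, function(x) as.character(x$sop), "")
    if (anyDuplicated(sops))
      note("<conversion>", "sop-distinct",
           paste("duplicate SOP instance UID:", sops[duplicated(sops)][1]))
    dirs <- dirname(names(per_file))
    for (d in unique(dirs)) {
      ser <- unique(vapply(per_file[dirs == d], function(x)
        as.character(x$series), ""))
      if (length(ser) != 1L)
        note(d, "series-per-folder",
             sprintf("folder holds %d distinct series UIDs", length(ser)))
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails)
              else data.frame(file = character(0), check = character(0),
                              message = character(0), stringsAsFactors = FALSE)
  list(ok = nrow(failures) == 0L && length(files) > 0L,
       nFiles = length(files), failures = failures)
}
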