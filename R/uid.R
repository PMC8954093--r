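# Content-hash identifier hierarchy.
#
# Every conversion derives its DICOM identifiers from the SHA-1 digest of
# the source file: the 160-bit digest, rendered as a decimal integer, is the
# patient ID (at most 49 digits); "1." + patientID is the study UID; the
# series UID appends the series index and the SOP UID the instance index.
# The "1." prefix mirrors the reference derivation and is not an assigned
# organization root.

# Base-16 -> base-10 schoolbook conversion on digit vectors; keeps the
# implementation independent of bignum libraries (openssl::bignum is used as
# an oracle in the tests).
#' @noRd
.hexToDecimal <- function(hex) {
  hex <- tolower(gsub("^0x", "", hex))
  if (!nzchar(hex) || grepl("[^0-9a-f]", hex)) stop("not a hex string: ", hex)
  nib <- strtoi(strsplit(hex, "")[[1]], base = 16L)
  dec <- 0L  # decimal digits, least significant first
  for (d in nib) {
    # dec = dec * 16 + d
    dec <- dec * 16L
    dec[1] <- dec[1] + d
    carry <- 0L
    for (i in seq_along(dec)) {
      v <- dec[i] + carry
      dec[i] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      dec <- c(dec, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  while (length(dec) > 1L && dec[length(dec)] == 0L) dec <- dec[-length(dec)]
  paste(rev(dec), collapse = "")
}

#' Derive a patient identifier from file content
#'
#' Hashes the complete byte stream of the source file (or several files, in
#' lexicographic name order, folded into one digest) with SHA-1 and renders
#' the digest as an unsigned base-10 integer with no leading zeros. The
#' result is at most 49 characters, within the DICOM LO value limit.
#'
#' @param path one or more existing files, or a single directory whose
#'   files are hashed in lexicographic name order.
#' @return decimal string.
#' @examples
#' f <- tempfile(); writeLines("a", f)
#' derivePatientID(f)
#' @export
derivePatientID <- function(path) {
  if (length(path) == 1L && dir.exists(path))
    path <- list.files(path, full.names = TRUE)
  path <- path[order(basename(path))]
  if (length(path) == 0L) stop("derivePatientID: no files to hash")
  if (any(!file.exists(path)))
    stop("derivePatientID: no such file: ", path[!file.exists(path)][1])
  if (sum(file.size(path)) == 0)
    stop("derivePatientID: refusing to hash an empty byte stream")
  con <- NULL
  hex <- if (length(path) == 1L) {
    con <- file(path, "rb")
    on.exit(close(con))
    as.character(openssl::sha1(con))
  } else {
    # fold multiple files into one digest by hashing the stream of their
    # concatenated contents (read incrementally)
    tmp <- tempfile()
    out <- file(tmp, "wb")
    for (p in path) {
      inc <- file(p, "rb")
      while (length(chunk <- readBin(inc, "raw", 8L * 1024L * 1024L)))
        writeBin(chunk, out)
      close(inc)
    }
    close(out)
    con <- file(tmp, "rb")
    on.exit({ close(con); unlink(tmp) })
    as.character(openssl::sha1(con))
  }
  .hexToDecimal(hex)
}

#' Derive the study/series/SOP identifier bundle
#'
#' Builds the full identifier hierarchy from a decimal patient ID:
#' \code{study = "1." + patientID}, \code{series = study + "." + seriesIndex},
#' \code{sop = series + "." + instanceIndex}. Components that would push any
#' identifier past the 64-character DICOM UID limit are rejected rather than
#' truncated.
#'
#' @param patientID decimal string (no leading zero unless "0").
#' @param seriesIndex integer >= 0; the focal-plane index for whole-slide
#'   conversions, 0 for volume conversions.
#' @param instanceIndex integer >= 0, sequential within a series.
#' @return a \linkS4class{UIDSet}.
#' @examples
#' deriveUIDs("7", 0, 0)
#' @export
deriveUIDs <- function(patientID, seriesIndex, instanceIndex) {
  if (!grepl("^(0|[1-9][0-9]*)$", patientID))
    stop("patientID: must be decimal text without a leading zero: ", patientID)
  seriesIndex <- as.integer(seriesIndex)
  instanceIndex <- as.integer(instanceIndex)
  if (is.na(seriesIndex) || seriesIndex < 0L)
    stop("seriesIndex: must be a non-negative integer")
  if (is.na(instanceIndex) || instanceIndex < 0L)
    stop("instanceIndex: must be a non-negative integer")
  study <- paste0("1.", patientID)
  series <- paste0(study, ".", seriesIndex)
  sop <- paste0(series, ".", instanceIndex)
  if (nchar(study) > 64L)
    stop(sprintf("studyUID exceeds 64 characters (%d): %s", nchar(study), study))
  if (nchar(series) > 64L)
    stop(sprintf("seriesUID exceeds 64 characters (%d): %s", nchar(series), series))
  if (nchar(sop) > 64L)
    stop(sprintf("sopUID exceeds 64 characters (%d): %s", nchar(sop), sop))
  new("UIDSet", patientID = patientID, studyUID = study,
      seriesUID = series, sopUID = sop)
}
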