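test_that("instance planning is channel-major and exhaustive", {
  # the reference channel/z layouts, planned on small-XY stand-in volumes
  for (cz in list(c(3L, 46L, 138L), c(4L, 64L, 256L), c(3L, 56L, 168L),
                  c(1L, 1L, 1L))) {
    v <- tinyVolume(C = cz[1], Z = cz[2], xy = 16L)
    plan <- planInstances(v)
    expect_identical(nrow(plan), cz[3])
    expect_identical(plan$instance, seq_len(cz[3]) - 1L)
  }

  v <- tinyVolume(C = 2L, Z = 3L, T = 2L)
  plan <- planInstances(v)
  # channel slowest, then z, then t
  expect_identical(plan$channel, rep(0:1, each = 6L))
  expect_identical(plan$z, rep(rep(0:2, each = 2L), times = 2L))
  expect_identical(plan$t, rep(0:1, times = 6L))

  # property: count == C*Z*T over random axis sizes
  set.seed(50)
  for (i in 1:10) {
    d <- sample(1:8, 3, replace = TRUE)
    v <- tinyVolume(C = d[1], Z = d[2], T = d[3], xy = 16L)
    expect_identical(nrow(planInstances(v)), as.integer(prod(d)))
  }
})

test_that("bit depth drives the Bits Allocated/Stored/High Bit triplet", {
  u <- deriveUIDs("7", 0, 0)
  triplets <- list("8" = c(8L, 8L, 7L), "12" = c(16L, 12L, 11L),
                   "16" = c(16L, 16L, 15L))
  for (bd in c(8L, 12L, 16L)) {
    v <- tinyVolume(C = 1L, Z = 1L, xy = 16L, bitDepth = bd)
    spec <- buildInstance(v, 0L, 0L, 0L, u)
    at <- spec@attributes
    get1 <- function(g, e) for (a in at) if (a$group == g && a$element == e)
      return(a$value)
    expect_identical(c(get1(0x0028, 0x0100), get1(0x0028, 0x0101),
                       get1(0x0028, 0x0102)),
                     triplets[[as.character(bd)]], info = bd)
    expect_identical(get1(0x0028, 0x0004), "MONOCHROME2")
    expect_identical(get1(0x0028, 0x0002), 1L)
  }
  expect_error(buildInstance(tinyVolume(), 5L, 0L, 0L, u), "outside")
})

test_that("the uncompressed path is lossless at every depth", {
  for (bd in c(8L, 12L, 16L)) {
    v <- tinyVolume(C = 2L, Z = 2L, xy = 24L, bitDepth = bd, seed = bd)
    u <- deriveUIDs("99", 0, 3)
    spec <- buildInstance(v, 1L, 0L, 0L, u)
    f <- tempfile(fileext = ".dcm")
    writeDicomInstance(spec, f)
    parsed <- readDicomInstance(f)
    slice <- dicomizer:::.dcmDecodeNativeSlice(parsed)
    expect_identical(as.integer(slice), as.integer(v@pixels[, , 2, 1, 1]))
    expect_identical(dicomizer:::.dsVal(parsed, "0008,0016"),
                     "1.2.840.10008.5.1.4.1.1.77.1.2")
    expect_identical(parsed$meta[["0002,0010"]], "1.2.840.10008.1.2.1")
    expect_identical(dicomizer:::.dsVal(parsed, "0008,0018"), "1.99.0.3")
  }
})

test_that("16-bit payloads serialize little-endian", {
  v <- tinyVolume(C = 1L, Z = 1L, xy = 16L, bitDepth = 16L, seed = 60)
  spec <- buildInstance(v, 0L, 0L, 0L, deriveUIDs("1", 0, 0))
  first <- v@pixels[1, 1, 1, 1, 1]
  expect_identical(as.integer(spec@pixelPayload[1:2]),
                   c(first %% 256L, first %/% 256L))
})

test_that("private tags round-trip the six acquisition values verbatim", {
  v <- tinyVolume(C = 1L, Z = 1L, xy = 16L)
  ch <- ChannelInfo("Channel:0:0", channelName = "DAPI",
                    illuminationType = "Epifluorescence",
                    magnification = "63x")
  spec <- buildInstance(v, 0L, 0L, 0L, deriveUIDs("5", 0, 0))
  spec <- embedPrivateTags(spec, ch, pixelSize = c(0.25, 0.25, 1.0))
  f <- tempfile(fileext = ".dcm")
  writeDicomInstance(spec, f)
  parsed <- readDicomInstance(f)
  val <- function(el) dicomizer:::.dsVal(parsed, sprintf("0011,%04X", el))
  expect_identical(val(0x1001), "DAPI")
  expect_identical(val(0x1002), "XYCZT")
  expect_identical(val(0x1003), "Epifluorescence")
  expect_match(val(0x1004), "0.25", fixed = TRUE)
  expect_match(val(0x1004), "um", fixed = TRUE)
  expect_identical(val(0x1005), "Channel:0:0")
  expect_identical(val(0x1006), "63x")
  expect_identical(val(0x0010), "DICOMIZER MICROSCOPY")

  # absent metadata writes empty values, not missing elements
  bare <- embedPrivateTags(buildInstance(v, 0L, 0L, 0L, deriveUIDs("5", 0, 0)),
                           ChannelInfo("c0"))
  f2 <- tempfile(fileext = ".dcm")
  writeDicomInstance(bare, f2)
  p2 <- readDicomInstance(f2)
  expect_identical(dicomizer:::.dsVal(p2, "0011,1003"), "")
})

test_that("full volume conversion emits C*Z*T coherent instances", {
  conv <- clsmConversion()
  m <- conv$manifest
  expect_identical(nrow(m$files), 15L)  # 3 channels x 5 z
  expect_length(list.files(conv$out, pattern = "\\.dcm$"), 15L)

  # all share study/series; SOP UIDs distinct and sequential
  expect_identical(m$seriesUID, paste0(m$studyUID, ".0"))
  expect_identical(m$files$sopUID,
                   paste0(m$seriesUID, ".", seq_len(15L) - 1L))

  # spot-check instance ordering: first file is channel 0, z 0
  first <- readDicomInstance(file.path(conv$out, m$files$file[1]))
  expect_identical(dicomizer:::.dsVal(first, "0020,0013"), "1")
  expect_identical(dicomizer:::.dsVal(first, "0010,0020"), m$patientID)

  # single-slice conversion: one file, instance index 0
  one <- makeClsmVolume(1, 1, xy = 16, bitDepth = 8, seed = 61)
  out1 <- tempfile()
  m1 <- convertVolume(one, out1)
  expect_identical(nrow(m1$files), 1L)
  expect_match(m1$files$sopUID[1], "\\.0\\.0$")
})

test_that("conversion round-trips pixels losslessly through files", {
  f <- makeClsmVolume(2, 2, xy = 24, bitDepth = 12, seed = 62)
  v <- readVolume(f)
  out <- tempfile()
  m <- convertVolume(f, out)
  for (i in seq_len(nrow(m$files))) {
    row <- m$files[i, ]
    parsed <- readDicomInstance(file.path(out, row$file))
    slice <- dicomizer:::.dcmDecodeNativeSlice(parsed)
    expect_identical(as.integer(slice),
                     as.integer(v@pixels[, , row$channel + 1L, row$z + 1L,
                                         row$t + 1L]))
    expect_identical(dicomizer:::.dsVal(parsed, "0028,0101"), 12L)
  }
})
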