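test_that("sniffing dispatches on structure, never on extension", {
  expect_identical(sniffSource(clsmFixture())@detectedKind, "volume")

  mrc <- makeEmStack(3, xy = 16, container = "mrc", seed = 40,
                     path = tempfile(fileext = ".bin"))
  expect_identical(sniffSource(mrc)@detectedKind, "em_stack")

  emt <- makeEmStack(3, xy = 16, container = "tiff", seed = 41)
  expect_identical(sniffSource(emt)@detectedKind, "em_stack")

  expect_identical(sniffSource(wsiFixture())@detectedKind, "pyramid")

  flat <- makeWsiPyramid(1, 2, c(600, 520), zPlanes = 1, seed = 42,
                         omexml = FALSE, path = tempfile(fileext = ".tif"))
  expect_identical(sniffSource(flat)@detectedKind, "unrecognized_pyramid")

  zb <- tempfile()
  file.create(zb)
  err <- tryCatch(sniffSource(zb), error = identity)
  expect_s3_class(err, "dicomizer_format_error")
  expect_match(conditionMessage(err), basename(zb), fixed = TRUE)
  expect_error(sniffSource(tempfile()), "no such path")
})

test_that("volumes read back with XYCZT axes and channel metadata", {
  v <- readVolume(clsmFixture())
  d <- dim(v@pixels)
  expect_identical(d[3], 3L)   # C
  expect_identical(d[4], 5L)   # Z
  expect_identical(d[5], 1L)   # T
  expect_identical(bitDepth(v), 16L)
  chans <- channelInfo(v)
  expect_identical(vapply(chans, function(c) c@channelName, ""),
                   c("DAPI", "FITC", "TRITC"))
  expect_identical(chans[[1]]@illuminationType, "Epifluorescence")
  expect_equal(v@pixelSize, c(0.25, 0.25, 1.0))
})

test_that("EM stacks become C = T = 1 volumes with Z sections", {
  f <- makeEmStack(7, xy = 24, container = "tiff", seed = 43)
  v <- readVolume(f)
  expect_identical(dim(v@pixels), c(24L, 24L, 1L, 7L, 1L))
  expect_identical(bitDepth(v), 8L)

  m <- makeEmStack(7, xy = 24, container = "mrc", seed = 43)
  vm <- readVolume(m)
  expect_identical(dim(vm@pixels), c(24L, 24L, 1L, 7L, 1L))
})

test_that("a single-page grayscale TIFF is the identity volume", {
  set.seed(44)
  page <- matrix(sample.int(256, 16 * 16, TRUE) - 1L, 16, 16)
  f <- tempfile(fileext = ".tif")
  dicomizer:::.tiffWrite(f, list(list(pixels = page, bits = 8L)))
  v <- readVolume(f)
  expect_identical(dim(v@pixels), c(16L, 16L, 1L, 1L, 1L))
  expect_identical(v@pixels[, , 1, 1, 1], t(page))
})

test_that("PNG slice directories are read in lexicographic order", {
  d <- file.path(tempdir(), "png_stack")
  dir.create(d, showWarnings = FALSE)
  set.seed(45)
  slices <- lapply(1:3, function(i) matrix(runif(16 * 16), 16, 16))
  # write out of order; names sort 01, 02, 03
  png::writePNG(slices[[2]], file.path(d, "slice_02.png"))
  png::writePNG(slices[[1]], file.path(d, "slice_01.png"))
  png::writePNG(slices[[3]], file.path(d, "slice_03.png"))
  v <- readVolume(d)
  expect_identical(dim(v@pixels)[4], 3L)
  for (i in 1:3)
    expect_identical(v@pixels[, , 1, i, 1],
                     t(matrix(as.integer(round(slices[[i]] * 255)), 16, 16)))
})

test_that("pyramids read back with sorted levels and focal planes", {
  p <- readPyramid(wsiFixture())
  expect_identical(levelWidths(p), c(1024L, 256L, 64L, 16L, 4L))
  expect_equal(vapply(pyramidLevels(p), function(l) l@downsample, 1),
               c(1, 4, 16, 64, 256))
  expect_identical(nZPlanes(p), 2L)
  # adjacent level ratios all 4 (the stacked-slide spacing pattern)
  w <- levelWidths(p)
  expect_true(all(w[-length(w)] / w[-1] == 4))

  two_z <- readPyramid(makeWsiPyramid(2, 2, c(96, 64), zPlanes = 2, seed = 46))
  expect_identical(nZPlanes(two_z), 2L)
})

test_that("pyramidalize halves until min dimension fits one tile", {
  # independent oracle: plain halving loop
  expectedLevels <- function(w, h, ts = 512L) {
    dims <- list(c(w, h))
    while (min(dims[[length(dims)]]) > ts)
      dims[[length(dims) + 1L]] <- dims[[length(dims)]] %/% 2L
    dims
  }
  for (wh in list(c(4096L, 4096L), c(1200L, 900L), c(520L, 520L), c(512L, 512L))) {
    flat <- makeWsiPyramid(1, 2, wh, zPlanes = 1, seed = 47, omexml = FALSE,
                           path = tempfile(fileext = ".tif"))
    out <- pyramidalize(flat, out = tempfile(fileext = ".ome.tiff"))
    p <- readPyramid(out)
    got <- lapply(pyramidLevels(p), function(l) c(l@width, l@height))
    expect_identical(got, expectedLevels(wh[1], wh[2]),
                     info = paste(wh, collapse = "x"))
  }
})

test_that("pyramidalize output survives a JPEG round trip and re-run", {
  flat <- makeWsiPyramid(1, 2, c(1200, 900), zPlanes = 1, seed = 48,
                         omexml = FALSE, path = tempfile(fileext = ".tif"))
  out <- pyramidalize(flat, out = tempfile(fileext = ".ome.tiff"))
  p <- readPyramid(out)

  orig <- dicomizer:::.tiffRead(flat)$pages[[1]]$pixels
  base <- getRegion(pyramidLevels(p)[[1]], 1, 1, 1, 1200, 900)
  expect_identical(dim(base), c(900L, 1200L, 3L))
  expect_lt(mean(abs(base - orig)), 10)

  # quality flag is recorded in the output metadata
  desc <- dicomizer:::.tiffRead(out, decode = FALSE)$pages[[1]]$description
  expect_equal(dicomizer:::.omeParse(desc)$jpegQuality, 90)

  # structural idempotence: pyramidalizing the output reproduces the level list
  out2 <- pyramidalize(out, out = tempfile(fileext = ".ome.tiff"), force = TRUE)
  p2 <- readPyramid(out2)
  expect_identical(lapply(pyramidLevels(p2), function(l) c(l@width, l@height)),
                   lapply(pyramidLevels(p), function(l) c(l@width, l@height)))

  # collision safety
  expect_error(pyramidalize(flat, out = out), "overwrite")
  expect_silent(pyramidalize(flat, out = out, overwrite = TRUE))
})
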