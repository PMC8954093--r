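# The TIFF container layer is exercised against tiff::readTIFF (libtiff) as
# an independent decoder wherever libtiff can read the layout.

test_that("striped grayscale pages round-trip and match libtiff", {
  set.seed(3)
  pages <- list(matrix(sample.int(256, 24 * 32, TRUE) - 1L, 24, 32),
                matrix(sample.int(256, 24 * 32, TRUE) - 1L, 24, 32))
  f <- tempfile(fileext = ".tif")
  dicomizer:::.tiffWrite(f, lapply(pages, function(p)
    list(pixels = p, bits = 8L, photometric = 1L)))

  own <- dicomizer:::.tiffRead(f)
  expect_length(own$pages, 2L)
  expect_identical(own$pages[[1]]$pixels, pages[[1]])
  expect_identical(own$pages[[2]]$pixels, pages[[2]])

  lib <- tiff::readTIFF(f, all = TRUE)
  for (i in 1:2)
    expect_identical(array(as.integer(round(lib[[i]] * 255)), dim(lib[[i]])),
                     pages[[i]])
})

test_that("16-bit pages serialize little-endian and read back exactly", {
  set.seed(4)
  page <- matrix(sample.int(65536, 16 * 16, TRUE) - 1L, 16, 16)
  f <- tempfile(fileext = ".tif")
  dicomizer:::.tiffWrite(f, list(list(pixels = page, bits = 16L, photometric = 1L)))
  expect_identical(dicomizer:::.tiffRead(f)$pages[[1]]$pixels, page)
  lib <- tiff::readTIFF(f)
  expect_identical(matrix(as.integer(round(lib * 65535)), nrow(lib)), page)
})

test_that("tiled RGB pages pad edges on write and crop on read", {
  set.seed(5)
  px <- array(sample.int(256, 70 * 50 * 3, TRUE) - 1L, dim = c(50, 70, 3))
  f <- tempfile(fileext = ".tif")
  dicomizer:::.tiffWrite(f, list(list(pixels = px, bits = 8L, tile_size = 32L)))
  got <- dicomizer:::.tiffRead(f)$pages[[1]]
  expect_true(got$tiled)
  expect_identical(got$pixels, px)
  lib <- tiff::readTIFF(f)
  expect_identical(array(as.integer(round(lib * 255)), dim(lib)), px)
})

test_that("JPEG-compressed tiles decode within a small error", {
  # smooth gradient, where baseline JPEG at quality 90 stays close
  g <- outer(seq(0, 1, length.out = 64), seq(0, 1, length.out = 96))
  px <- array(0L, dim = c(64, 96, 3))
  for (k in 1:3) px[, , k] <- as.integer(round(g * 200) + 20 * k)
  f <- tempfile(fileext = ".tif")
  dicomizer:::.tiffWrite(f, list(list(pixels = px, bits = 8L, tile_size = 64L,
                                      compression = "jpeg", quality = 90)))
  got <- dicomizer:::.tiffRead(f)$pages[[1]]$pixels
  expect_identical(dim(got), dim(px))
  expect_lt(mean(abs(got - px)), 3)
})

test_that("SubIFD pyramids preserve structure and per-level pixels", {
  mk <- function(w, h) array(sample.int(256, h * w * 3, TRUE) - 1L, c(h, w, 3))
  set.seed(6)
  base <- mk(64, 128); l1 <- mk(32, 64); l2 <- mk(16, 32)
  f <- tempfile(fileext = ".tif")
  dicomizer:::.tiffWrite(f, list(list(
    pixels = base, bits = 8L, tile_size = 32L, description = "<OME/>",
    subifds = list(list(pixels = l1, bits = 8L, tile_size = 32L, subfiletype = 1L),
                   list(pixels = l2, bits = 8L, tile_size = 32L, subfiletype = 1L)))))
  got <- dicomizer:::.tiffRead(f)
  expect_length(got$pages, 1L)
  expect_length(got$pages[[1]]$subifds, 2L)
  expect_identical(got$pages[[1]]$pixels, base)
  expect_identical(got$pages[[1]]$subifds[[1]]$pixels, l1)
  expect_identical(got$pages[[1]]$subifds[[2]]$pixels, l2)
  expect_identical(got$pages[[1]]$description, "<OME/>")
})

test_that("non-TIFF and zero-byte inputs fail with clear diagnostics", {
  junk <- tempfile()
  writeBin(as.raw(1:64), junk)
  expect_error(dicomizer:::.tiffRead(junk), "not a TIFF")
  zb <- tempfile()
  file.create(zb)
  expect_error(dicomizer:::.tiffRead(zb), "zero-byte")
  expect_error(dicomizer:::.tiffRead(tempfile()), "no such file")
})
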