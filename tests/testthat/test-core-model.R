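test_that("invalid objects are rejected with a diagnostic naming the field", {
  px <- array(0L, dim = c(4, 4, 2, 1, 1))
  expect_error(ImageVolume(px, bitDepth = 10L), "bitDepth")
  expect_error(ImageVolume(px, bitDepth = 8L,
                           channels = list(ChannelInfo("c1"))), "channels")
  hot <- px; hot[1] <- 300L
  expect_error(ImageVolume(hot, bitDepth = 8L), "pixels")
  expect_error(ImageVolume(array(0L, dim = c(4, 4)), bitDepth = 8L), "pixels")
  expect_error(ChannelInfo(""), "channelID")

  lv <- function(w, h) PyramidLevel(list(array(0L, dim = c(h, w, 3))))
  expect_error(PyramidImage(list(lv(64, 32), lv(64, 32))), "widths")
  expect_error(PyramidImage(list(lv(64, 32)), background = c(999L, 0L, 0L)),
               "background")
  mixed <- list(PyramidLevel(list(array(0L, c(16, 32, 3)),
                                  array(0L, c(16, 32, 3)))),
                PyramidLevel(list(array(0L, c(8, 16, 3)))))
  expect_error(PyramidImage(mixed), "z-plane")

  expect_error(new("UIDSet", patientID = "7", studyUID = "2.7",
                   seriesUID = "2.7.0", sopUID = "2.7.0.0"), "studyUID")
  expect_error(new("UIDSet", patientID = "7", studyUID = "1.7",
                   seriesUID = "1.8.0", sopUID = "1.8.0.0"), "seriesUID")

  expect_error(new("DicomInstanceSpec", attributes = list(),
                   transferSyntaxUID = "1.2.840.10008.1.2.1",
                   sopClassUID = "not-a-uid",
                   pixelPayload = raw(2), frameCount = 1L), "sopClassUID")
  expect_error(new("DicomInstanceSpec", attributes = list(),
                   transferSyntaxUID = "1.2.840.10008.1.2.4.50",
                   sopClassUID = "1.2.840.10008.5.1.4.1.1.77.1.6",
                   pixelPayload = list(raw(2), raw(2)), frameCount = 3L),
               "frameCount")
})

test_that("UID grammar accepts dotted decimals and rejects malformed strings", {
  expect_true(all(isValidUID(c("0", "1.2.840.10008.1.2.1",
                               "1.186355337916212766286352571899677090176885900481.0.23"))))
  expect_false(any(isValidUID(c("", "1.", ".1", "1..2", "1.02", "01", "1.2a",
                                strrep("1.1", 33)))))
})

test_that("pyramid region access is pure and pads beyond edges", {
  set.seed(7)
  plane <- array(sample.int(256, 20 * 30 * 3, replace = TRUE) - 1L,
                 dim = c(20, 30, 3))
  lvl <- PyramidLevel(list(plane))
  a <- getRegion(lvl, 1, 5, 5, 10, 8)
  b <- getRegion(lvl, 1, 5, 5, 10, 8)
  expect_identical(a, b)
  expect_identical(a, plane[5:12, 5:14, , drop = FALSE])

  # region hanging off the right/bottom edge: inside matches, outside is background
  r <- getRegion(lvl, 1, 25, 15, 10, 10, background = c(9L, 8L, 7L))
  expect_identical(r[1:6, 1:6, ], plane[15:20, 25:30, , drop = FALSE])
  expect_true(all(r[, 7:10, 1] == 9L & r[, 7:10, 2] == 8L & r[, 7:10, 3] == 7L))
  expect_true(all(r[7:10, , 1] == 9L))

  # fully out-of-bounds region is pure background
  off <- getRegion(lvl, 1, 100, 100, 4, 4, background = c(1L, 2L, 3L))
  expect_true(all(off[, , 2] == 2L))
})

test_that("accessors expose volume and pyramid geometry", {
  v <- tinyVolume(C = 3L, Z = 4L, T = 2L)
  expect_identical(nChannels(v), 3L)
  expect_identical(nZPlanes(v), 4L)
  expect_identical(nTimepoints(v), 2L)
  expect_identical(bitDepth(v), 8L)
  expect_length(channelInfo(v), 3L)

  lv <- function(w, h, z = 1L)
    PyramidLevel(replicate(z, array(0L, dim = c(h, w, 3)), simplify = FALSE),
                 downsample = 64 / w)
  p <- PyramidImage(list(lv(64, 32, 2), lv(16, 8, 2)))
  expect_identical(levelWidths(p), c(64L, 16L))
  expect_identical(nZPlanes(p), 2L)
  expect_length(pyramidLevels(p), 2L)
})
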