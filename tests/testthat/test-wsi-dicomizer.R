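test_that("level planning reproduces the reference gap-fill counts", {
  plan5 <- planLevels(readPyramid(wsiFixture()))   # 5 levels, 4x spacing
  expect_identical(nrow(planEntries(plan5)), 10L)

  # 9 levels at 2x: every synthesized candidate except the deepest collides
  dims9 <- dicomizer:::.planLevelDims(4096L %/% 2L^(0:8), 2816L %/% 2L^(0:8))
  expect_identical(nrow(dims9), 10L)

  # 6 levels at 4x: no collisions, count doubles
  dims6 <- dicomizer:::.planLevelDims(4096L %/% 4L^(0:5), 2048L %/% 4L^(0:5))
  expect_identical(nrow(dims6), 12L)

  # single level: native + its half, no collision possible
  dims1 <- dicomizer:::.planLevelDims(600L, 520L)
  expect_identical(nrow(dims1), 2L)
  expect_identical(dims1$out_width, c(600L, 300L))
  expect_identical(dims1$out_height, c(520L, 260L))
})

test_that("planned dimensions are unique, decreasing, and stable", {
  p <- planEntries(planLevels(readPyramid(wsiFixture())))
  expect_false(any(duplicated(p[, c("out_width", "out_height")])))
  expect_true(all(diff(p$out_width) < 0))
  # native entries preserve their source level's dimensions
  nat <- p[p$mode == "native", ]
  w <- levelWidths(readPyramid(wsiFixture()))
  expect_identical(nat$out_width, w)
  # synthesized entries are exact floor halves of their source
  syn <- p[p$mode == "synthesized", ]
  expect_identical(syn$out_width, w[syn$source_level] %/% 2L)

  # re-planning the plan's own native entries reproduces the plan
  again <- dicomizer:::.planLevelDims(nat$out_width, nat$out_height)
  expect_identical(again, p)
})

test_that("adding a level never decreases the planned count", {
  set.seed(70)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    ratio <- sample(c(2, 3, 4), 1)
    base_w <- sample(500:3000, 1)
    base_h <- sample(500:3000, 1)
    w <- as.integer(base_w %/% ratio^(0:(n - 1)))
    h <- as.integer(base_h %/% ratio^(0:(n - 1)))
    keep <- w >= 1L & h >= 1L
    w <- w[keep]; h <- h[keep]
    before <- nrow(dicomizer:::.planLevelDims(w, h))
    w2 <- c(w, max(1L, w[length(w)] %/% as.integer(ratio)))
    h2 <- c(h, max(1L, h[length(h)] %/% as.integer(ratio)))
    if (w2[length(w2)] < w[length(w)]) {
      after <- nrow(dicomizer:::.planLevelDims(w2, h2))
      expect_gte(after, before)
    }
  }
})

test_that("tiling covers the grid with background-padded edge tiles", {
  set.seed(71)
  plane <- array(sample.int(256, 513 * 512 * 3, TRUE) - 1L, c(512, 513, 3))
  lvl <- PyramidLevel(list(plane))
  bg <- c(255L, 255L, 255L)
  acc <- function(x0, y0, w, h) getRegion(lvl, 1, x0, y0, w, h, background = bg)

  t4 <- tileLevel(acc, 1024, 1024, "native")
  expect_length(t4, 4L)

  t2 <- tileLevel(acc, 513, 512, "native")
  expect_length(t2, 2L)
  # brute-force reference padder for the second tile
  ref <- array(rep(bg, each = 512 * 512), c(512, 512, 3))
  ref[, 1, ] <- plane[, 513, ]
  expect_identical(t2[[2]], ref)
  expect_true(all(t2[[2]][, 2:512, ] == 255L))
  expect_identical(t2[[1]], plane[, 1:512, ])
})

test_that("synthesized tiles are 2x area averages of the source", {
  # constant source region averages to the same constant
  flat <- PyramidLevel(list(array(77L, c(1024, 1024, 3))))
  acc <- function(x0, y0, w, h) getRegion(flat, 1, x0, y0, w, h)
  tl <- tileLevel(acc, 512, 512, "synthesized")
  expect_length(tl, 1L)
  expect_true(all(tl[[1]] == 77L))

  # independent oracle: nested-loop 2x2 block means on a random region
  set.seed(72)
  src <- array(sample.int(256, 64 * 64 * 3, TRUE) - 1L, c(64, 64, 3))
  expected <- array(0L, c(32, 32, 3))
  for (y in 1:32) for (x in 1:32) for (k in 1:3) {
    block <- src[(2 * y - 1):(2 * y), (2 * x - 1):(2 * x), k]
    expected[y, x, k] <- as.integer(floor(sum(block) / 4 + 0.5))
  }
  expect_identical(dicomizer:::.areaHalve(src), expected)
})

test_that("JPEG frames preserve cardinality, size, and near-constant pixels", {
  tiles <- replicate(3, array(128L, c(512, 512, 3)), simplify = FALSE)
  frames <- encodeFrames(tiles, jpegQuality = 90)
  expect_length(frames, 3L)
  for (fr in frames) {
    dec <- jpeg::readJPEG(fr)
    expect_identical(dim(dec)[1:2], c(512L, 512L))
    expect_lte(max(abs(round(dec * 255) - 128)), 2)
  }
})

test_that("WSI instances carry the multi-frame attributes", {
  entry <- list(out_width = 1024L, out_height = 1024L, mode = "native")
  frames <- replicate(4, as.raw(c(1, 2)), simplify = FALSE)
  u <- deriveUIDs("42", 0, 0)
  spec <- buildWsiInstance(entry, frames, u,
                           pyramidMeta = list(deviceMaker = "ACME"))
  at <- spec@attributes
  get1 <- function(g, e) for (a in at) if (a$group == g && a$element == e)
    return(a$value)
  expect_identical(get1(0x0028, 0x0008), "4")
  expect_identical(get1(0x0028, 0x0004), "YBR_FULL_422")
  expect_identical(get1(0x0028, 0x0002), 3L)
  expect_identical(get1(0x0048, 0x0006), 1024L)
  expect_identical(get1(0x0020, 0x9311), "TILED_FULL")
  expect_identical(get1(0x0011, 0x1011), "ACME")
  expect_identical(spec@sopClassUID, "1.2.840.10008.5.1.4.1.1.77.1.6")
  expect_identical(spec@transferSyntaxUID, "1.2.840.10008.1.2.4.50")

  expect_error(buildWsiInstance(entry, frames[1:3], u), "inconsistent")
})

test_that("frame counts follow ceil(W/512) * ceil(H/512) for arbitrary dims", {
  set.seed(73)
  u <- deriveUIDs("42", 0, 0)
  for (i in 1:25) {
    w <- sample(1:3000, 1); h <- sample(1:3000, 1)
    n <- ceiling(w / 512) * ceiling(h / 512)
    frames <- replicate(n, raw(2), simplify = FALSE)
    spec <- buildWsiInstance(list(out_width = w, out_height = h), frames, u)
    expect_identical(spec@frameCount, as.integer(n))
    if (n > 1L)
      expect_error(buildWsiInstance(list(out_width = w, out_height = h),
                                    frames[-1], u), "inconsistent")
  }
})

test_that("a full WSI conversion emits one folder per z, one file per level", {
  conv <- wsiConversion()
  m <- conv$manifest
  expect_length(m$folders, 2L)
  expect_identical(nrow(m$levels), 10L)
  for (folder in names(m$folders)) {
    files <- list.files(file.path(conv$out, folder), pattern = "\\.dcm$")
    expect_length(files, 10L)
  }
  # series UID = study + "." + z index; shared study
  expect_identical(m$folders$stack_00$seriesUID, paste0(m$studyUID, ".0"))
  expect_identical(m$folders$stack_01$seriesUID, paste0(m$studyUID, ".1"))

  # minimal case: 1 z-plane, 1 level -> 1 folder with 2 files
  tiny <- makeWsiPyramid(1, 2, c(96, 64), zPlanes = 1, seed = 74)
  outT <- tempfile()
  mT <- convertWsi(tiny, outT)
  expect_length(mT$folders, 1L)
  expect_length(list.files(file.path(outT, "stack_00")), 2L)
})

test_that("stitching frames back reproduces the level exactly in geometry", {
  conv <- wsiConversion()
  pyr <- readPyramid(wsiFixture())
  base <- pyramidLevels(pyr)[[1]]
  parsed <- readDicomInstance(file.path(conv$out, "stack_00", "level_00.dcm"))
  ts <- 512L
  cols <- ceiling(base@width / ts)
  rows <- ceiling(base@height / ts)
  expect_length(parsed$frames, cols * rows)
  canvas <- array(0L, c(rows * ts, cols * ts, 3L))
  k <- 1L
  for (ty in seq_len(rows)) for (tx in seq_len(cols)) {
    dec <- round(jpeg::readJPEG(parsed$frames[[k]]) * 255)
    canvas[((ty - 1L) * ts + 1L):(ty * ts),
           ((tx - 1L) * ts + 1L):(tx * ts), ] <- dec
    k <- k + 1L
  }
  stitched <- canvas[seq_len(base@height), seq_len(base@width), , drop = FALSE]
  orig <- getRegion(base, 1, 1, 1, base@width, base@height)
  expect_identical(dim(stitched), dim(orig))
  expect_lt(mean(abs(stitched - orig)), 10)
})
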