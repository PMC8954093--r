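# Shared fixture cache: expensive generated files and conversions are built
# once per test run and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, build(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small in-memory volume without touching disk
tinyVolume <- function(C = 2L, Z = 3L, T = 1L, xy = 16L, bitDepth = 8L,
                       seed = 42L) {
  set.seed(seed)
  px <- array(sample.int(2^bitDepth, xy * xy * C * Z * T, replace = TRUE) - 1L,
              dim = c(xy, xy, C, Z, T))
  ImageVolume(px, bitDepth = bitDepth)
}

# standard small fixtures reused by several test files
clsmFixture <- function() cached("clsm_3c_5z", function()
  makeClsmVolume(3, 5, xy = 32, bitDepth = 16, seed = 11,
                 path = file.path(tempdir(), "fix_clsm.ome.tiff")))

wsiFixture <- function() cached("wsi_5l_2z", function()
  makeWsiPyramid(5, 4, c(1024, 512), zPlanes = 2, seed = 13,
                 path = file.path(tempdir(), "fix_wsi.ome.tiff")))

wsiConversion <- function() cached("wsi_conv", function() {
  out <- file.path(tempdir(), "fix_wsi_dcm")
  manifest <- convertWsi(wsiFixture(), out)
  list(out = out, manifest = manifest)
})

clsmConversion <- function() cached("clsm_conv", function() {
  out <- file.path(tempdir(), "fix_clsm_dcm")
  manifest <- convertVolume(clsmFixture(), out)
  list(out = out, manifest = manifest)
})
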