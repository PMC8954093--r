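# dicomizer

Converts microscopy images from open containers into standard DICOM, for
imaging scientists and archive engineers who need vendor-neutral storage of
confocal, electron-microscopy and whole-slide data.

Three pathways, matching how DICOM models the modalities:

| Input | Output |
|---|---|
| Multichannel confocal z-stack (OME-TIFF, XYCZT) | one single-frame **VL Microscopic Image Storage** instance per (channel, z, t) slice, uncompressed, explicit VR little-endian |
| Serial EM section stack (multi-page TIFF, MRC2014) | same pathway with C = T = 1: one instance per section |
| Pyramidal RGB whole-slide image (OME-TIFF / tiled TIFF) | tiled multi-frame **VL Whole Slide Microscopy Image Storage** series, baseline JPEG frames, one folder per focal plane |

Two ideas carry the package beyond plain repackaging:

**Gap-filled level planning.** Sparse pyramids (adjacent levels 4× apart)
force viewers to fetch many tiles between magnifications. For every stored
level `L` the planner emits `L` natively *and*, unless a stored level
already sits there (±1 px on both axes), a synthesized level at
`floor(dim(L)/2)` built by 2×2 area-averaging double-size source regions.
A 5-level 4×-spaced pyramid thus emits 10 levels; a 9-level 2×-spaced one
emits 10 (all but the deepest candidate collide and are dropped).

**Content-hash identifiers.** The SHA-1 digest of the source file, rendered
in decimal, is the patient ID (≤ 49 digits). Then
`study = "1." + patientID`, `series = study + "." + z`,
`sop = series + "." + instance` — deterministic, collision-free in
practice, and never truncated (overflow past 64 characters is an error).

A flat tiled TIFF whose reduced levels are missing or unreadable is first
rebuilt as a pyramidal OME-TIFF (`pyramidalize()`: successive 2× area
averaging down to one tile, JPEG tiles at quality 90) and then converted.

## Worked example

```r
library(dicomizer)

# a synthetic 5-level, 4x-spaced slide with 2 focal planes
slide <- makeWsiPyramid(5, 4, c(1024, 512), zPlanes = 2, seed = 7,
                        path = "slide.ome.tiff")
readPyramid(slide)
#> PyramidImage: 5 level(s), 2 z-plane(s)
#>   level 0: 1024 x 512 (downsample 1)
#>   level 1: 256 x 128 (downsample 4)
#>   level 2: 64 x 32 (downsample 16)
#>   level 3: 16 x 8 (downsample 64)
#>   level 4: 4 x 2 (downsample 256)

planLevels(readPyramid(slide))
#> LevelPlan with 10 entries
#>  source_level        mode out_width out_height
#>             1      native      1024        512
#>             1 synthesized       512        256
#>             2      native       256        128
#>             ...                                  (10 rows: 5 native + 5 synthesized)

m <- dicomize(slide, "slide_dcm")
#> [dicomize] sniffed slide.ome.tiff as pyramid [ome-tiff] (0.01 s)
#> [dicomize] WSI pathway: 2 folders x 10 levels (1.64 s)

m$patientID
#> [1] "369650900563892684885057688168871447696978791884"
str(m$folders$stack_00$files[[1]])
#> List of 6
#>  $ file  : chr "level_00.dcm"
#>  $ mode  : chr "native"
#>  $ width : int 1024
#>  $ height: int 512
#>  $ frames: int 2
#>  $ sopUID: chr "1.369650900563892684885057688168871447696978791884.0.0"

validateDicom("slide_dcm")$ok
#> [1] TRUE
```

The 1024×512 base level cuts into `ceil(1024/512) * ceil(512/512) = 2`
frames; each focal plane gets its own `stack_NN/` folder holding one
multi-frame file per planned level, all sharing the content-derived study
UID. The written files are ordinary DICOM: pydicom and any Part 10 viewer
read them back, and `validateDicom()` re-checks parseability, UID grammar,
frame-grid arithmetic and frame decodability.

Volumes work the same way:

```r
vol <- makeClsmVolume(3, 46, xy = 64, bitDepth = 16, seed = 1)
m <- convertVolume(vol, "vol_dcm")
nrow(m$files)
#> [1] 138          # 3 channels x 46 optical sections
```

A shell front end with `convert` / `pyramidalize` / `generate` / `validate`
subcommands lives at `inst/scripts/dicomizer.R` (exit codes: 0 success,
1 conversion failure, 2 unrecognized input).

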