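---
title: "Converting microscopy images to DICOM: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting microscopy images to DICOM: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Microscope vendors ship pixel data in dozens of proprietary containers.
Radiology solved the same interoperability problem decades ago with DICOM,
and DICOM today defines information objects for visible-light microscopy:
*VL Microscopic Image Storage* (SOP class `1.2.840.10008.5.1.4.1.1.77.1.2`)
for single-frame micrographs and *VL Whole Slide Microscopy Image Storage*
(`...77.1.6`) for tiled gigapixel slides. This package implements the three
conversion pathways that cover the common modalities in cell-imaging work:

1. **Confocal (CLSM-like) volumes** — multichannel z-stacks, conceptually
   five-dimensional (X, Y, channel, z, time; "XYCZT"). Each (channel, z, t)
   optical section becomes one single-frame instance.
2. **Serial EM (FIB-SEM-like) stacks** — sequences of 2D sections (here:
   multi-page TIFF or MRC2014). Treated as a volume with C = T = 1.
3. **Whole-slide pyramids** — multi-resolution tiled RGB images, optionally
   with several focal planes, converted into tiled multi-frame series with
   synthesized intermediate levels.

Proprietary readers are out of scope: the package ingests open stand-in
containers (OME-TIFF, plain TIFF, MRC2014, PNG slice directories) and ships
a deterministic generator for all three input classes, so everything is
testable without external data.

# The volume pathway

A volume is modeled as a 5-axis integer array in fixed X,Y,C,Z,T order;
ingestion reorders whatever the container stored. Planning enumerates
slices channel-major (channel slowest, then z, then t), so a C-channel,
Z-section stack yields exactly C x Z instances — a 3-channel, 46-plane
volume produces 138 files, a 4-channel, 64-plane volume 256.

Each instance is written uncompressed under the explicit VR little-endian
transfer syntax (`1.2.840.10008.1.2.1`), `MONOCHROME2`, one sample per
pixel. The stored bit depth drives the standard triplet (Bits Allocated,
Bits Stored, High Bit): (8, 8, 7), (16, 12, 11) or (16, 16, 15). Twelve-bit
data travels in a 16-bit container with Bits Stored = 12, matching how
acquisition software reports such data. The uncompressed path is exactly
lossless, which the tests assert bit-for-bit at all three depths.

Because the public dictionary has no elements for microscope acquisition
detail, six values travel in one private block (group `0011`, creator
`DICOMIZER MICROSCOPY`): channel name, dimension order (always "XYCZT"),
illumination type, physical pixel size with units, channel id, and
magnification. Absent values are written empty rather than omitted, so
read-back is uniform.

# The whole-slide pathway

## Gap-filling level planning

Slide viewers fetch tiles level by level; when adjacent stored levels
differ by 4x per axis (common in some scanners), the jump between
magnifications forces the viewer to fetch and shrink many more tiles than
needed — a *zoom gap*. The planner closes these gaps with two passes per
stored level: the level itself is emitted at native resolution, and a
second, synthesized rendition is produced at floor(width/2) x
floor(height/2) by reading double-size source regions and 2x
area-averaging them.

A synthesized candidate is dropped when an existing stored level already
sits at those dimensions, within one pixel on both axes — the tolerance
absorbs floor-division off-by-ones between a stored half-resolution level
and a computed one. Remaining exact dimension duplicates collapse keeping
the first. The arithmetic consequences, which the acceptance tests pin:

* 5 stored levels spaced 4x emit 10 levels (no candidate collides);
* 6 stored levels spaced 4x emit 12;
* 9 stored levels spaced 2x emit 10 (every candidate except the deepest
  collides with the next stored level);
* a single stored level emits 2.

Levels smaller than one tile are kept: they cost one frame each and the
6-to-12 pattern above requires them.

## Tiling and encoding

Each output level is cut into 512 x 512 tiles, row-major, edge tiles padded
with the pyramid background (white, the brightfield slide background; the
choice is ours — no canonical padding value exists for edge tiles). Tiles
are encoded as independent baseline JPEG streams at quality 90 and
encapsulated as the frames of one multi-frame instance per (focal plane,
level), with a basic offset table. Attributes follow the WSI IOD:
`YBR_FULL_422`, three samples per pixel, Rows = Columns = 512,
`TILED_FULL` frame organization, and the level's full dimensions in Total
Pixel Matrix Columns/Rows. Output is laid out one folder per focal plane
(`stack_00/...`), one file per level (`level_00.dcm` the largest), series
index = focal-plane index.

## The OME-TIFF fallback

A tiled RGB TIFF whose reduced-resolution pages are absent or unreadable
cannot be converted directly. `pyramidalize()` re-tiles the base level and
successively 2x area-average downsamples it until the smaller dimension
fits one tile (levels below one tile add no navigation value on this path),
writing a SubIFD-organized OME-TIFF with JPEG tiles at quality 90 — the
quality is recorded in the output metadata. The result is accepted by the
normal pyramid reader, and re-running the fallback on its own output
reproduces the same level dimension list (structural idempotence). The
downsampling filter is 2 x 2 area averaging with round-half-up: the
choice is deterministic, alias-free, and preserves constant regions
exactly.

# Identifiers

Every conversion hashes the complete byte stream of its source file with
SHA-1 and renders the 160-bit digest as a decimal integer: that string (at
most 49 digits) is the patient ID. The hierarchy is then purely mechanical:

```
study  = "1." + patientID
series = study + "." + seriesIndex     (focal plane for WSI, 0 for volumes)
sop    = series + "." + instanceIndex  (sequential within the series)
```

The worst case (49 digits, series 99, instance 999) reaches 58 characters,
inside the 64-character UID limit; components that would overflow are
rejected by name, never truncated. The `1.` prefix is not a registered
organization root — these UIDs are content-addressed identifiers, globally
unique in practice because SHA-1 collisions are. For multi-file sources
(slice directories) the files are hashed in lexicographic name order into a
single digest.

A note on transfer syntax bookkeeping: converters are sometimes seen
advertising the implicit VR syntax (`1.2.840.10008.1.2`) in summaries while
writing explicit VR files; here every file records exactly what it is
written in, explicit VR little-endian (`1.2.840.10008.1.2.1`) on the volume
path.

# Containers written and read

No installed R package writes tiled, SubIFD-organized, JPEG-compressed
OME-TIFF or DICOM Part 10, so both container layers are implemented here at
byte level, deliberately minimal:

* **TIFF**: classic little-endian writer (striped grayscale 8/16-bit,
  tiled RGB with optional per-tile JPEG, SubIFD level chains, OME-XML in
  ImageDescription); reader additionally handles BigTIFF and both byte
  orders. Unknown compressions fail loudly.
* **MRC2014**: dimensions from header words 1-3, pixel type from the mode
  word, `MAP ` stamp at offset 208. Modes 0/1/2/6 map to bit depths
  8/16/16/16; float data (mode 2) is min-max rescaled into the 16-bit
  range; signed mode-1 data with negatives is shifted so the minimum
  becomes 0; mode-0 bytes are read as unsigned 0..255, the EM convention.
* **DICOM**: explicit VR little-endian datasets, file meta group, native
  OB/OW or encapsulated pixel data. The parser reads exactly what the
  writer emits and feeds the validator.

Interoperability is tested, not assumed: libtiff (`tiff::readTIFF`) decodes
the striped and tiled uncompressed outputs bit-exactly, and the test suite
cross-checks written DICOM against pydicom when a Python interpreter is
available (both pydicom and tifffile accept the files, including pyramid
level structure and encapsulated frames).

# The fixture generator

The generator emulates the three input classes structurally: per-channel
Gaussian blob textures over a z-profile for confocal volumes (with channel
names, illumination, wavelengths in OME-XML), speckle-plus-gradient
sections for EM stacks, and a smooth H&E-like RGB texture for pyramids,
rendered per level from continuous functions of base-level coordinates so
every level depicts the same scene. Focal planes share geometry but differ
in texture phase. Texture content is irrelevant to every count this
package asserts; it only needs to be non-constant and smooth enough that
JPEG round-trip error bounds (mean absolute error below 10 at quality 90)
are meaningful. Outputs are byte-identical for identical arguments: the
generator seeds R's RNG locally and the writers embed no timestamps.

What the fixtures do **not** emulate: vendor metadata blocks, compression
artifacts of real scanner output, stain variability, file-size or timing
characteristics. Passing tests therefore demonstrate structural and
arithmetic correctness of the conversion — counts, layouts, identifiers,
attribute constants, pixel fidelity — not robustness to the quirks of any
vendor's writer.

# Scale choices and numerical notes

Unit tests run pyramids around 1024 x 512 and volumes at 16-64 pixel XY —
the conversion arithmetic (instance counts, level planning, tile grids) is
scale-free, so small fixtures pin the same behavior that holds at full
size. The acceptance script uses 4096-wide pyramids and full-size
channel/section counts (46 x 3, 64 x 4, 361 sections, 11 focal planes). Area averaging uses integer round-half-up, making synthesized
pixels platform-independent. Tie-breaks in level deduplication keep the
earlier (larger-source) entry. Degenerate requests — a synthesized level
that would reach zero pixels, a UID past 64 characters, a truncated pixel
stream — are rejected with diagnostics naming the offending field, file or
byte counts.

# Known limitations

* Only the two transfer syntaxes the pipelines emit are read back;
  arbitrary third-party DICOM is out of scope for the validator.
* The WSI path assumes 8-bit RGB pyramids; grayscale slides are promoted
  to RGB on read.
* Time-series volumes (T > 1) are supported by extension of the XYCZT
  order, though typical confocal exports carry T = 1.
* No ICC profiles, label/macro images, sparse tiling, or DICOM network
  services; the validator replaces archive indexing as the read-back check.
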