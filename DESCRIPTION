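Package: dicomizer
Title: DICOMization of Confocal, Whole-Slide and FIB-SEM Microscopy Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Converts open microscopy image containers into standard DICOM.
    Multichannel confocal (CLSM-like) z-stack volumes and serial electron
    microscopy (FIB-SEM-like) section stacks become one single-frame VL
    Microscopic Image Storage instance per (channel, z, t) slice; pyramidal
    whole-slide images become tiled multi-frame VL Whole Slide Microscopy
    Image Storage series, with intermediate resolution levels synthesized by
    2x downsampling to close zoom gaps between sparsely spaced pyramid
    levels. Patient, study, series and SOP identifiers are derived from a
    SHA-1 content hash of the source file. Includes a pyramidal OME-TIFF
    fallback writer for flat tiled TIFF inputs, a deterministic synthetic
    fixture generator for all three modalities, and a read-back validator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    jpeg,
    png,
    openssl,
    xml2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'dicomizer-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'tiff-io.R'
    'mrc-io.R'
    'ome-xml.R'
    'uid.R'
    'dicom-write.R'
    'dicom-read.R'
    'ingest.R'
    'fixtures.R'
    'volume-dicomizer.R'
    'wsi-dicomizer.R'
    'validate.R'
    'cli.R'
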