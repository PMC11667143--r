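Package: mprct
Title: Multiplanar Reconstruction of CT DICOM Series with Hybrid Inter-Slice Interpolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rebuilds 3D volumes from axial CT DICOM series and re-slices them
    into coronal and sagittal views (multiplanar reconstruction, MPR). Reads and
    writes single-frame uncompressed part-10 DICOM, orders slices along the scan
    axis, classifies inter-slice intervals as contiguous, gapped, or overlapping,
    and synthesizes missing planes with a hybrid scheme: weighted bilinear
    interpolation for non-edge pixels and Catmull-Rom bicubic interpolation for
    intensity edges. Includes the measurement tool suite of a clinical viewer
    (length, angle, probe, rectangular/elliptical/freehand ROI statistics,
    window/level, invert, magnify), sub-pixel half-maximum edge localization for
    validation, and a synthetic CT phantom generator with known ground-truth
    geometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
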