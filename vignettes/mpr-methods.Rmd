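---
title: "Multiplanar reconstruction from CT DICOM series: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplanar reconstruction from CT DICOM series: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mprct)
```

## The problem

A CT acquisition delivers a stack of axial slices as single-frame DICOM
files. Radiological reading, however, routinely needs the orthogonal
reformats — coronal and sagittal views — which only exist after the stack is
reassembled into a 3D volume. Real series complicate this in three ways:
slices arrive in arbitrary file order, the z sampling can be non-uniform
(gaps where the scanner stepped further than the slab thickness, overlaps or
duplicates where it stepped less), and key tags are sometimes degenerate
(a spacing-between-slices tag of 0, or missing position tags). `mprct`
implements the whole chain — DICOM parsing, geometric ordering, interval
classification, volume building with hybrid inter-slice interpolation, view
extraction, and quantitative validation — as composable, tested R functions.

## Pipeline and assumptions

1. **Parsing** (`read_series`). Single-frame, uncompressed little-endian CT
   objects only; compressed transfer syntaxes are rejected with a clear
   error rather than silently mis-read. Stored integer pixel values are kept
   as stored; the modality rescale to Hounsfield units
   (`HU = stored × slope + intercept`) is a separate, explicit step so that
   interpolation operates on stored values, as in a viewer pipeline where
   windowing follows reconstruction. Missing optional tags are represented
   as absent, never silently defaulted.
2. **Ordering** (`order_slices`). The scan axis is the cross product of the
   row and column direction cosines; each slice's scalar position is the
   signed projection of Image Position (Patient) onto that normal. This
   handles oblique acquisitions, where the raw z coordinate would not.
   Ties are broken by instance number, then slice location; when positions
   are absent entirely, the same chain (instance number, then location)
   orders the stack.
3. **Interval classification** (`classify_intervals`). Each gap between
   consecutive slices is compared with the *nominal spacing* and labelled
   `contiguous`, `gap`, or `overlap` (the latter includes duplicated
   positions).
4. **Volume building** (`build_volume`). Overlaps are deduplicated first,
   then gaps are filled back to nominal sampling, then the stack is expanded
   to the requested depth; the three stages are described below.
5. **Views and measurement** (`extract_plane`, `measure_extent`). Views are
   exported unresampled with anisotropic per-axis spacings, so millimetre
   measurements are exact; an optional bicubic resampling to square pixels
   exists for display (`magnify` provides the kernel).

## The nominal z sampling unit

The nominal spacing is resolved as: **slice thickness** when present and
positive; else the spacing-between-slices tag when positive; else the median
observed step. Thickness comes first because it is the physical slab width
and therefore the natural z sampling unit: a series of 0.625 mm slabs placed
5.0 mm apart genuinely leaves 4.375 mm of unsampled tissue between slabs and
must be treated as gapped, even though its spacing tag reads a plausible
5.0 mm. Conversely a series with thickness 5.0 mm and a degenerate spacing
tag of 0 — a pattern that occurs in clinical exports — still resolves to a
sensible 5.0 mm nominal. The cost of this ordering is that deliberately
overlapping reconstructions (thickness larger than the reconstruction
interval) classify as overlapped and are thinned to the nominal grid; for
this package's purpose — building a geometrically uniform volume — that is
the intended behaviour, but users processing overlapping-recon series who
want every plane kept should pass an explicit `target_depth` after
inspecting `interval_labels`.

The classification tolerance defaults to 1 % of the nominal spacing with a
floor of 0.01 mm (`default_spacing_tol`): wide enough to absorb the
floating-point noise of decimal-string tags, far too narrow to mask a real
gap (the smallest clinically plausible mismatch is a whole missing slice).

## The z step and plane budget

The expansion factor from `n` available planes to a requested depth `d` is
`z_step = d / n`. When `d = n` nothing is synthesized — original planes pass
through bit-exactly. Otherwise each of the `n − 1` intervals receives
`round(z_step) − 1` synthesized planes and the integer remainder is pushed
onto the trailing intervals (cascading backwards if rounding overshoots), so
the output depth equals `d` exactly and the rule is deterministic. Requests
with `d < n` are rejected: decimating acquired data is out of scope.
Synthesized planes sit at strictly interior fractional positions
`w_j = j/(m+1)`, so an anchor plane is never re-synthesized. Gap filling
runs *before* depth expansion so that a gapped series and its contiguous
twin produce volumes of identical shape — coronal and sagittal aspect
correctness requires uniform z sampling. Whether these two stages should
instead be interleaved is not decidable from first principles; the two-phase
order is the simplest rule that preserves both uniformity and anchor
fidelity.

## Hybrid interpolation

For a synthesized plane at position `w` between anchors `V_i` and `V_{i+1}`:

* **Non-edge pixels** use a weighted bilinear average: half weight on the
  pixel itself, a quarter on each lateral neighbour, scaled by `(1−w)` for
  the current plane and `w` for the next. The weights sum to 1, so constant
  inputs are reproduced exactly and every output is a convex combination of
  anchor values (no overshoot).
* **Array-boundary pixels** (first/last pixel of a row) have one lateral
  neighbour; the weights become 0.75/0.25. The lateral axis is the flattened
  row-major pixel index, and first/last-*column* pixels are treated as
  boundary pixels so no neighbourhood ever wraps across a row — the
  behaviour a flat pixel-buffer implementation should have but can silently
  get wrong.
* **Intensity-edge pixels** — central-difference gradient magnitude above
  `edge_threshold` (default 100 stored units, i.e. 100 HU at slope 1; image
  borders are never flagged) — use cubic convolution along z instead of
  lateral averaging, which preserves sharp boundaries that lateral smoothing
  would soften. The kernel is Catmull-Rom (`a = −0.5`): exactly the cubic
  whose coefficients are determined by values and finite-difference
  derivatives, and the same kernel behind the package's bicubic form
  `f(u,v) = Σ a_ij u^i v^j` (`bicubic_eval`, used by `magnify`). The two
  z-outer knots are the neighbouring acquired planes when they exist and
  replicate-clamped anchors otherwise; with clamped knots the response is
  monotone in `w`, with genuine outer knots mild overshoot is possible —
  the standard Catmull-Rom trade-off, accepted for its edge fidelity.

"Edge" is a genuinely ambiguous term in inter-slice interpolation schemes:
it can mean the array boundary or an intensity edge. This package
implements both readings — the 0.75/0.25 variant at array boundaries, the
cubic kernel at intensity edges — because each addresses a real failure
mode, and exposes the intensity threshold (`edge_threshold`) so the cubic
branch can be disabled (`Inf`) or made aggressive.

Interpolation runs in double precision on stored values; rounding back to
integers (half-even) happens only at DICOM export (`volume_to_slices`).

## Overlap deduplication

Overlapping or duplicated slices are binned by quantizing z to multiples of
the nominal spacing; within each bin the slice with the lowest instance
number — acquisition order — is kept. Selection, not averaging: blending
near-coincident slices would smear motion differences into ghosting, and
keeping the earliest acquisition is reproducible and explainable.

## Views, reference lines, and display

Indices are 1-based `(row, col, plane)` throughout, matching R; the JSON
sidecars written next to exported volumes and PNGs record this convention.
Coronal views fix a volume row (pixels = plane × column), sagittal views fix
a column (pixels = plane × row); both carry `spacing_plane` vertically, so
`rows × spacing_v` equals the volume's physical z extent exactly.
Reference lines are the intersections of one view's plane with another,
reduced to horizontal/vertical segments in the orthogonal-plane case.
The display transform is the linear window/level map onto 8-bit
(`[0, 255]`), with half-even rounding; 8 bits matches the web-canvas class
of viewer this engine models. Pan/zoom/stack-scroll gestures reduce to crop
arithmetic, `magnify`, and `extract_plane` with a varying index; no separate
kernels are needed.

## The phantom and what the tests do (and do not) show

`generate_phantom` emits genuine DICOM series with analytically known
geometry: a block (default 20.0 × 20.0 × 15.0 mm), sphere, or gradient
insert in a 64 × 64 matrix at 0.9 mm pixels, 40 slices at
thickness = spacing = 3.75 mm — parameters chosen from the middle of the
clinical envelope this engine targets (512 × 512 matrices at 0.78–0.98 mm
pixels, thickness 0.625–5.0 mm, spacing 0–5.0 mm; the matrix is scaled down
16-fold so the full suite runs in seconds, and nothing in the algorithms
depends on matrix size). Spacing modes reproduce the awkward acquisition
patterns: contiguous, gapped (every third slice dropped), thin-slice/
wide-spacing (thickness 0.625 mm at 5.0 mm steps), overlapping, duplicated,
and the zero-spacing-tag regime. Insert edges sit on half-pixel boundaries
by default so half-maximum localization is exact by construction
(`offgrid = TRUE` randomizes them for robustness testing); insert and
background default to stored 1224 and 24 — +200 and −1000 HU under the
written rescale (slope 1, intercept −1024).

Validation (`mpr_validate`) measures the insert by half-maximum sub-pixel
localization — the profile's crossing of `(min + max)/2`, linearly
interpolated between samples — on the axial source view and on the
reconstructed coronal/sagittal views, and reports the mean absolute error
`(1/n) Σ |M_i − G_i|`. The volume depth is refined to `2n − 1` planes by
default so that half the output planes are synthesized and the hybrid
interpolation is genuinely on the measurement path.

What passing these tests shows: the geometry bookkeeping is exact (anchor
planes bit-identical, views index-consistent, physical extents preserved),
the interpolation kernels satisfy their mathematical contracts, and the
reconstruction does not displace high-contrast edges. What they do not
show: behaviour on anatomical texture, beam-hardening or scatter artefacts,
gantry-tilted geometries, or the low-contrast regime where half-maximum
localization itself becomes ill-defined — the phantom's binary contrast is
deliberately the easy case that isolates reconstruction error from
segmentation error.

## Numerical and degenerate-input choices

* Half-maximum edge localization requires a non-flat profile; flat profiles
  raise a structured "no edges" condition, and `measure_extent` converts
  fewer-than-two crossings into "structure not found".
* ROI membership is pixel-centre-inside (no partial-area weighting): simple
  and checkable against a brute-force oracle. Polygon tests use even-odd
  ray casting via `pracma::inpolygon`.
* A single-pixel row has no lateral neighbour at all: interpolation
  degenerates to the plain linear blend `(1−w)V_i + wV_{i+1}`.
* Zero-length profiles, out-of-range indices, empty directories, and
  zero-file series each raise a dedicated condition class with a distinct
  CLI exit code; the zero-file case is an explicit branch of the protocol,
  not an accident.
* All randomness (phantom noise) flows from a single integer seed; every
  pipeline stage is deterministic, and builds are byte-reproducible.

## Problem sizes

The shipped test suite and the acceptance script use 64 × 64 × 40 phantoms
(the validation case), 16–32 pixel matrices for geometry and I/O tests, 200
random 4 × 4 grids for the bicubic oracle comparison, 100 randomized
interpolation cases, and 1,000 random voxels for cross-view consistency —
sizes chosen so the whole suite completes in well under a minute while still
exercising every code path; all scale linearly if enlarged.

## Known limitations

* Single-frame, uncompressed little-endian CT only; no enhanced multi-frame
  objects, no DICOMweb, no anonymization.
* One series per directory; no splitting by Series Instance UID, no
  localizer detection (a scout image mixed into a stack will be rejected as
  mixed orientation rather than filtered out).
* No gantry-tilt correction and no oblique reformats; views are strictly
  orthogonal.
* No maximum-intensity projection or volume rendering.
* Wall-clock timings printed by `mpr_build` and the `bench` subcommand are
  hardware-dependent diagnostics, deliberately kept out of result files.
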