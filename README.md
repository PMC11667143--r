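# mprct

Multiplanar reconstruction (MPR) of CT DICOM series in R: read a directory of
axial slices, rebuild the 3D volume — ordering slices along the scan axis and
handling gaps, overlaps, and degenerate spacing tags — and re-slice it into
coronal and sagittal views with correct physical aspect. The package also
provides the measurement tool suite of a clinical viewer (length, angle,
probe, ROI statistics, window/level, invert, magnify), sub-pixel half-maximum
edge localization for quantitative validation, and a synthetic CT phantom
generator with analytically known geometry.

It is aimed at researchers building or validating medical-image viewing
pipelines who need a scriptable, fully tested MPR reference implementation
rather than an interactive viewer.

## Method

**Slice geometry.** Slices are sorted by the signed projection of Image
Position (Patient) onto the slice normal (ties: instance number, then slice
location). Each inter-slice interval is classified against the nominal z
sampling unit — the slice thickness, falling back to the spacing tag and then
to the median observed step — as *contiguous*, *gap* (Δz larger), or
*overlap* (Δz smaller, including duplicates). Overlaps are deduplicated by
z-binning (keeping the lowest instance number); gaps are filled with
synthesized planes so z sampling returns to nominal; the volume is then
expanded to the requested depth with a z step `target_depth / n_planes`.

**Hybrid inter-slice interpolation.** A synthesized plane at fractional
position `w ∈ (0,1)` between anchor planes `V_i` and `V_{i+1}` is computed
per pixel `k`:

- non-edge pixels — weighted bilinear averaging over the pixel and its two
  lateral neighbours:

  ```
  P(k)     = P_i(k) + P_{i+1}(k)
  P_i(k)   = (1−w)(0.5 V_i[k] + 0.25 V_i[k−1] + 0.25 V_i[k+1])
  P_{i+1}(k) =  w (0.5 V_{i+1}[k] + 0.25 V_{i+1}[k−1] + 0.25 V_{i+1}[k+1])
  ```

- array-boundary pixels (one neighbour missing) — weights 0.75 for the pixel
  and 0.25 for the available neighbour, under the same `(1−w)/w` split;
- intensity-edge pixels (central-difference gradient magnitude above a
  threshold, default 100 stored units) — cubic convolution (Catmull-Rom,
  `a = −0.5`) along z, the 1D restriction of the bicubic form
  `f(u,v) = Σ a_ij u^i v^j` used for in-plane resampling (magnify).

**Validation statistic.** A structure is measured by half-maximum sub-pixel
localization on the axial source view (ground truth `G`) and on the
reconstructed coronal/sagittal views (measured `M`); accuracy is the mean
absolute error `(1/n) Σ |M_i − G_i|` in millimetres.

## Worked example

```r
library(mprct)
spec <- phantom_spec()                       # 64x64, 40 slices, 20x20x15 mm block
series_dir <- file.path(tempdir(), "demo")
invisible(write_series(generate_phantom(spec), series_dir))

slices <- read_series(series_dir)
geom <- classify_intervals(order_slices(slices))
print(geom)
#> <series_geometry 40 slices, nominal spacing 3.75 mm; intervals: contiguous=39>

vol <- build_volume(geom, target_depth = 79) # refine z sampling 2x
print(vol)
#> <volume_grid 64x64x79, spacing 0.9x0.9x1.875 mm, 40 original / 39 interpolated planes>

ax <- extract_plane(vol, "axial", 39)
measure_extent(ax, "h", 32)                  # block width on the axial view
#> [1] 19.8
co <- extract_plane(vol, "coronal", 32)
measure_extent(co, "h", 39)                  # same width on the coronal view
#> [1] 19.8
measure_extent(co, "v", 32)                  # block height along z
#> [1] 15

res <- mpr_validate(slices)
print(res$set)
#> <measurement_set n=6, mean abs error 0 mm>
```

The in-plane width reads 19.8 mm — the true 20.0 mm quantized to whole
0.9 mm pixels, i.e. within half a pixel of truth — and, decisively for MPR
fidelity, the reconstructed coronal view reproduces the axial measurement
exactly (error 0 mm over 6 pairs, far below the 0.05 mm acceptance margin).
The z extent of 15 mm is exact because the block's z faces lie midway
between slice centres.

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mprct", package = "mprct"))')
Rscript $CLI phantom --out /tmp/series --seed 7
Rscript $CLI build --in /tmp/series --out /tmp/vol --target-depth 79
Rscript $CLI validate --out /tmp/validation.csv
```

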