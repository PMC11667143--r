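# Synthetic CT phantom generator: DICOM series with analytically known
# geometry. Emulates the envelope of clinical peripheral-artery CT series
# (512x512 axial matrices, pixel spacing ~0.78-0.98 mm, slice thickness
# 0.625-5.0 mm, spacing 0-5.0 mm) at a scaled-down default matrix so tests
# run in seconds, covering contiguous, gapped, overlapping, duplicate, and
# zero-spacing-tag configurations.
#
# Patient coordinates: x along image columns, y along rows, z along the scan
# axis; orientation is canonical axial (1,0,0, 0,1,0). The first pixel centre
# of each slice sits at (0, 0, z_slice).

#' Phantom specification
#'
#' @param matrix_size Length-2 `(rows, cols)`; default 64x64 (a scaled-down
#'   stand-in for clinical 512x512 matrices, so suites run in seconds).
#' @param n_slices Number of base slice positions.
#' @param pixel_spacing In-plane spacing, mm/pixel (default 0.9, mid clinical
#'   range).
#' @param slice_thickness Slab thickness, mm.
#' @param spacing_between_slices Value written to the spacing tag; may be 0
#'   (degenerate-tag regime) or `NA` to omit the tag. Slice positions use
#'   this step when positive, else the thickness.
#' @param insert `"block"`, `"sphere"`, or `"gradient"`.
#' @param insert_extents Length-3 physical extents `(x, y, z)` mm (sphere:
#'   all equal to the diameter; gradient: ignored).
#' @param insert_value,background_value Stored units. Defaults 1224 / 24 =
#'   +200 / -1000 HU under slope 1, intercept -1024.
#' @param noise_sigma Gaussian noise on stored values (truncated to the valid
#'   integer range); 0 = noise-free.
#' @param seed RNG seed (fixed seed => bit-identical series).
#' @param spacing_mode `"contiguous"`, `"gap"` (every `gap_drop_every`-th
#'   slice dropped), `"overlap"` (extra slices at sub-spacing offsets), or
#'   `"duplicate"` (repeated z positions).
#' @param gap_drop_every Drop period for `"gap"` mode.
#' @param offgrid Shift insert edges off the half-pixel grid (robustness
#'   testing); default keeps edges on half-pixel boundaries so half-maximum
#'   localization is unambiguous.
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(64, 64),
                         n_slices = 40,
                         pixel_spacing = 0.9,
                         slice_thickness = 3.75,
                         spacing_between_slices = slice_thickness,
                         insert = c("block", "sphere", "gradient"),
                         insert_extents = c(20, 20, 15),
                         insert_value = 1224,
                         background_value = 24,
                         noise_sigma = 0,
                         seed = 20240101,
                         spacing_mode = c("contiguous", "gap", "overlap", "duplicate"),
                         gap_drop_every = 3,
                         offgrid = FALSE) {
  insert <- match.arg(insert)
  spacing_mode <- match.arg(spacing_mode)
  if (noise_sigma < 0)
    mpr_error("noise_sigma must be >= 0", "mpr_spec_error")
  if (n_slices < 2)
    mpr_error("phantom needs at least 2 slices", "mpr_spec_error")
  if (pixel_spacing <= 0 || slice_thickness <= 0)
    mpr_error("pixel spacing and slice thickness must be positive", "mpr_spec_error")
  step <- if (!is.na(spacing_between_slices) && spacing_between_slices > 0)
    spacing_between_slices else slice_thickness
  fov <- c(matrix_size[2] * pixel_spacing,   # x
           matrix_size[1] * pixel_spacing,   # y
           n_slices * step)                  # z
  if (insert != "gradient" && any(insert_extents >= fov))
    mpr_error("insert extents must fit inside the physical field of view", "mpr_spec_error")
  structure(list(
    matrix_size = as.integer(matrix_size),
    n_slices = as.integer(n_slices),
    pixel_spacing = pixel_spacing,
    slice_thickness = slice_thickness,
    spacing_between_slices = spacing_between_slices,
    insert = insert,
    insert_extents = as.numeric(insert_extents),
    insert_value = insert_value,
    background_value = background_value,
    noise_sigma = noise_sigma,
    seed = as.integer(seed),
    spacing_mode = spacing_mode,
    gap_drop_every = as.integer(gap_drop_every),
    offgrid = isTRUE(offgrid)
  ), class = "phantom_spec")
}

# snap a coordinate onto the nearest half-sample boundary (k + 0.5) * spacing
.snap_half <- function(x, spacing) {
  (round(x / spacing - 0.5) + 0.5) * spacing
}

# insert bounds in patient mm: list(lo = c(x,y,z), hi = c(x,y,z))
.insert_bounds <- function(spec) {
  step <- if (!is.na(spec$spacing_between_slices) && spec$spacing_between_slices > 0)
    spec$spacing_between_slices else spec$slice_thickness
  centre <- c(
    (spec$matrix_size[2] - 1) / 2 * spec$pixel_spacing,
    (spec$matrix_size[1] - 1) / 2 * spec$pixel_spacing,
    (spec$n_slices - 1) / 2 * step
  )
  ext <- spec$insert_extents
  lo <- centre - ext / 2
  if (!spec$offgrid) {
    lo[1] <- .snap_half(lo[1], spec$pixel_spacing)
    lo[2] <- .snap_half(lo[2], spec$pixel_spacing)
    lo[3] <- .snap_half(lo[3], step)
  }
  list(lo = lo, hi = lo + ext, centre = centre, step = step)
}

#' Generate a phantom DICOM series (in memory)
#'
#' Samples the analytic insert at voxel centres: a voxel takes
#' `insert_value` when its centre lies inside the insert, else
#' `background_value`. Slice positions follow `spacing_mode`; Gaussian noise
#' (if any) is seeded so identical specs yield bit-identical series.
#'
#' @param spec A [phantom_spec()].
#' @return List of [slice_record()]s (unordered by z in the overlap /
#'   duplicate modes, matching real-world acquisition order).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  b <- .insert_bounds(spec)
  step <- b$step
  nr <- spec$matrix_size[1]; nc <- spec$matrix_size[2]

  base_z <- (seq_len(spec$n_slices) - 1) * step
  zs <- base_z
  inst <- seq_along(base_z)
  if (spec$spacing_mode == "gap") {
    keep <- seq_along(base_z) %% spec$gap_drop_every != 0
    keep[1] <- TRUE; keep[length(keep)] <- TRUE  # keep endpoints
    zs <- base_z[keep]; inst <- inst[keep]
  } else if (spec$spacing_mode == "overlap") {
    extra_at <- which(seq_along(base_z) %% 3 == 1 & seq_along(base_z) < spec$n_slices)
    zs <- c(base_z, base_z[extra_at] + 0.4 * step)
    inst <- c(inst, spec$n_slices + seq_along(extra_at))
  } else if (spec$spacing_mode == "duplicate") {
    dup_at <- which(seq_along(base_z) %% 5 == 1)
    zs <- c(base_z, base_z[dup_at])
    inst <- c(inst, spec$n_slices + seq_along(dup_at))
  }

  xs <- (seq_len(nc) - 1) * spec$pixel_spacing
  ys <- (seq_len(nr) - 1) * spec$pixel_spacing
  xm <- matrix(rep(xs, each = nr), nr, nc)
  ym <- matrix(rep(ys, nc), nr, nc)

  set.seed(spec$seed)
  lapply(seq_along(zs), function(i) {
    z <- zs[i]
    m <- matrix(spec$background_value, nr, nc)
    if (spec$insert == "block") {
      inside <- xm > b$lo[1] & xm < b$hi[1] & ym > b$lo[2] & ym < b$hi[2] &
        z > b$lo[3] & z < b$hi[3]
      m[inside] <- spec$insert_value
    } else if (spec$insert == "sphere") {
      r <- spec$insert_extents[1] / 2
      d2 <- (xm - b$centre[1])^2 + (ym - b$centre[2])^2 + (z - b$centre[3])^2
      m[d2 <= r^2] <- spec$insert_value
    } else { # gradient: linear ramp along x
      m <- spec$background_value +
        (spec$insert_value - spec$background_value) * xm / max(xs)
    }
    if (spec$noise_sigma > 0)
      m <- m + stats::rnorm(length(m), 0, spec$noise_sigma)
    m <- round(m)
    m[m < 0] <- 0; m[m > 65535] <- 65535
    storage.mode(m) <- "integer"
    slice_record(
      pixel_matrix = m,
      image_position = c(0, 0, z),
      orientation = c(1, 0, 0, 0, 1, 0),
      pixel_spacing = c(spec$pixel_spacing, spec$pixel_spacing),
      slice_thickness = spec$slice_thickness,
      spacing_between_slices = if (is.na(spec$spacing_between_slices)) NULL
        else spec$spacing_between_slices,
      instance_number = inst[i],
      slice_location = z,
      rescale_slope = 1,
      rescale_intercept = -1024,
      window_center = 200,
      window_width = 1600
    )
  })
}

#' Analytic ground-truth extents of the phantom insert
#'
#' @param spec A [phantom_spec()].
#' @return Named numeric `(x, y, z)` extents in mm. The gradient insert has
#'   no discrete extents and raises a `mpr_not_found` condition.
#' @export
ground_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$insert == "gradient")
    mpr_error("no discrete extents: gradient insert has no edges", "mpr_not_found")
  if (spec$insert == "sphere") {
    d <- spec$insert_extents[1]
    return(c(x = d, y = d, z = d))
  }
  c(x = spec$insert_extents[1], y = spec$insert_extents[2], z = spec$insert_extents[3])
}
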