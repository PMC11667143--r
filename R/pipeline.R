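# High-level pipeline: directory of DICOM slices -> ordered geometry ->
# volume -> views -> validation measurements. These are the functions the
# command-line front end wraps.

#' Build an MPR volume from a DICOM directory
#'
#' Runs the full protocol: read, order, classify intervals, deduplicate
#' overlaps, fill gaps, expand to the target depth. Wall-clock load/build
#' times are reported via `message()` as hardware-dependent diagnostics
#' only — they are never written into result files.
#'
#' @param input_dir Directory containing one DICOM series.
#' @param target_depth Output depth, or `"auto"` (default): number of planes
#'   after gap filling, i.e. z step 1 plus gap filling.
#' @param spacing_tol Interval-classification tolerance, mm
#'   (default [default_spacing_tol()]).
#' @param edge_threshold Gradient cutoff for the hybrid edge rule (stored
#'   units).
#' @param output_prefix Optional path prefix; when given the volume is
#'   exported via [write_volume_raw()].
#' @param quiet Suppress timing diagnostics.
#' @return A `volume_grid`.
#' @export
mpr_build <- function(input_dir, target_depth = "auto", spacing_tol = NULL,
                      edge_threshold = 100, output_prefix = NULL, quiet = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  slices <- read_series(input_dir)
  t1 <- proc.time()[["elapsed"]]
  geom <- order_slices(slices)
  geom <- classify_intervals(geom, spacing_tol)
  td <- if (identical(target_depth, "auto") || is.null(target_depth)) NULL
        else as.integer(target_depth)
  vol <- build_volume(geom, target_depth = td,
                      edge_threshold = edge_threshold, tolerance = spacing_tol)
  t2 <- proc.time()[["elapsed"]]
  if (!quiet) {
    message(sprintf("[timing diagnostic, hardware-dependent] load (T1 analogue): %.3f s",
                    t1 - t0))
    message(sprintf("[timing diagnostic, hardware-dependent] volume build (T2 analogue): %.3f s",
                    t2 - t1))
  }
  if (!is.null(output_prefix)) write_volume_raw(vol, output_prefix)
  vol
}

# centre of the insert along each volume axis: midpoint of the span where
# the axis sum profile exceeds its half-maximum (no generating spec needed)
.locate_structure <- function(volume) {
  v <- volume$voxels
  mid <- function(sums) {
    lev <- (min(sums) + max(sums)) / 2
    round(mean(range(which(sums > lev))))
  }
  list(
    row = mid(apply(v, 1, sum)),
    col = mid(apply(v, 2, sum)),
    plane = mid(apply(v, 3, sum))
  )
}

#' Cross-view validation on a phantom series
#'
#' The automated analogue of measuring one bony structure in all three
#' views: a synthetic insert's extents are measured by half-maximum sub-pixel
#' localization on the axial source view (ground truth `G`) and on the
#' reconstructed coronal and sagittal views (measured `M`), and the mean
#' absolute error `1/n * sum(|M_i - G_i|)` is computed. By default the
#' volume depth is refined to `2 * n_planes - 1` so the hybrid interpolation
#' actually synthesizes half of the output planes.
#'
#' @param slices List of [slice_record()]s (e.g. from [generate_phantom()]
#'   or [read_series()]).
#' @param target_depth Output depth; `NULL` (default) refines to
#'   `2 * n - 1` where `n` is the post-gap-fill plane count.
#' @param edge_threshold Gradient cutoff for the hybrid edge rule.
#' @param n_lines Number of parallel measurement lines per axis (centred on
#'   the structure).
#' @param spacing_tol Interval-classification tolerance, mm.
#' @return List: `set` (a `measurement_set`, coronal/sagittal vs axial),
#'   `measurements` (data frame, one row per tool reading),
#'   `z_consistency_mm` (|coronal z extent - sagittal z extent|),
#'   `volume`.
#' @export
mpr_validate <- function(slices, target_depth = NULL, edge_threshold = 100,
                         n_lines = 3, spacing_tol = NULL) {
  geom <- classify_intervals(order_slices(slices), spacing_tol)
  geom2 <- select_slices_overlap(geom, spacing_tol)
  filled <- fill_gaps(geom2, edge_threshold)
  n <- length(filled$planes)
  if (is.null(target_depth)) target_depth <- 2L * n - 1L
  vol <- build_volume(geom, target_depth = target_depth,
                      edge_threshold = edge_threshold, tolerance = spacing_tol)

  ctr <- .locate_structure(vol)
  offs <- seq_len(n_lines) - (n_lines + 1) / 2   # e.g. -1, 0, 1
  rows <- round(ctr$row + offs)
  cols <- round(ctr$col + offs)
  planes <- round(ctr$plane + offs)

  ax <- extract_plane(vol, "axial", ctr$plane)
  co <- extract_plane(vol, "coronal", ctr$row)
  sa <- extract_plane(vol, "sagittal", ctr$col)

  meas <- list()
  add <- function(tool, view, index, axis, line, value) {
    meas[[length(meas) + 1L]] <<- data.frame(
      tool = tool, view = view, index = index, axis = axis,
      line = line, value_mm = value, stringsAsFactors = FALSE)
  }

  g <- numeric(0); m <- numeric(0)
  for (r in rows) {  # x extents: axial rows vs coronal view rows (planes)
    add("extent", "axial", ctr$plane, "h", r, measure_extent(ax, "h", r))
  }
  for (p in planes) {
    add("extent", "coronal", ctr$row, "h", p, measure_extent(co, "h", p))
  }
  for (cc in cols) { # y extents: axial columns vs sagittal view rows
    add("extent", "axial", ctr$plane, "v", cc, measure_extent(ax, "v", cc))
  }
  for (p in planes) {
    add("extent", "sagittal", ctr$col, "h", p, measure_extent(sa, "h", p))
  }
  df <- do.call(rbind, meas)

  ax_x <- df$value_mm[df$view == "axial" & df$axis == "h"]
  co_x <- df$value_mm[df$view == "coronal"]
  ax_y <- df$value_mm[df$view == "axial" & df$axis == "v"]
  sa_y <- df$value_mm[df$view == "sagittal"]
  set <- error_margin(c(co_x, sa_y), c(ax_x, ax_y))

  z_co <- measure_extent(co, "v", ctr$col)
  z_sa <- measure_extent(sa, "v", ctr$row)
  df <- rbind(df,
    data.frame(tool = "extent", view = "coronal", index = ctr$row,
               axis = "v", line = ctr$col, value_mm = z_co),
    data.frame(tool = "extent", view = "sagittal", index = ctr$col,
               axis = "v", line = ctr$row, value_mm = z_sa))

  list(set = set, measurements = df,
       z_consistency_mm = abs(z_co - z_sa), volume = vol)
}
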