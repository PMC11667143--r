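# Volume assembly: overlap deduplication, gap filling back to uniform nominal
# sampling, then expansion to the requested depth with synthesized planes.
# Gap filling runs BEFORE depth expansion so a gapped series and its
# contiguous twin yield volumes of identical shape (coronal/sagittal aspect
# depends on uniform z sampling).

#' Deduplicate overlapping slices
#'
#' Slices are binned by quantizing their z position to multiples of the
#' nominal spacing; within each bin the slice with the lowest instance number
#' (acquisition order) is kept — selection, not blending. A series without
#' overlaps is returned unchanged.
#'
#' @param geometry Ordered `series_geometry`.
#' @param tolerance Spacing tolerance in mm (default [default_spacing_tol()]).
#' @return A `series_geometry` with strictly increasing z positions.
#' @export
select_slices_overlap <- function(geometry, tolerance = NULL) {
  stopifnot(inherits(geometry, "series_geometry"))
  ns <- geometry$nominal_spacing
  if (is.null(tolerance)) tolerance <- default_spacing_tol(ns)
  z <- geometry$z_positions
  bins <- round((z - z[1]) / ns)
  if (!anyDuplicated(bins)) return(geometry)
  inst <- vapply(geometry$slices, function(s)
    if (is.null(s$instance_number)) NA_real_ else as.numeric(s$instance_number), numeric(1))
  keep <- vapply(split(seq_along(z), bins), function(idx) {
    if (length(idx) == 1) return(idx)
    ii <- inst[idx]
    if (all(is.na(ii))) idx[1] else idx[which.min(ii)]
  }, numeric(1))
  keep <- sort(unname(keep))
  out <- geometry
  out$slices <- geometry$slices[keep]
  out$z_positions <- z[keep]
  out$interval_labels <- NULL
  classify_intervals(out, tolerance)
}

#' Fill gap intervals with synthesized planes
#'
#' Each gap interval of width `dz` receives `round(dz / nominal) - 1`
#' synthesized planes at uniform fractional positions, restoring
#' approximately nominal z sampling. Synthesized planes are flagged
#' `interpolated`; acquired planes keep their pixel data bit-exactly.
#'
#' @param geometry Ordered, classified `series_geometry`.
#' @param edge_threshold Gradient cutoff for [classify_edge_pixels()].
#' @return List with `planes` (list of matrices), `z` (mm positions),
#'   `provenance` (`"original"` / `"interpolated"`), and `source_index`
#'   (index into the kept slices, `NA` for synthesized planes).
#' @export
fill_gaps <- function(geometry, edge_threshold = 100) {
  stopifnot(inherits(geometry, "series_geometry"))
  if (is.null(geometry$interval_labels))
    geometry <- classify_intervals(geometry)
  slices <- geometry$slices
  z <- geometry$z_positions
  ns <- geometry$nominal_spacing
  n <- length(slices)
  mats <- lapply(slices, function(s) {
    m <- s$pixel_matrix; storage.mode(m) <- "double"; m
  })

  planes <- list(mats[[1]])
  zs <- z[1]
  prov <- "original"
  src <- 1L
  for (i in seq_len(n - 1)) {
    if (geometry$interval_labels[i] == "gap") {
      dz <- z[i + 1] - z[i]
      m <- max(round(dz / ns) - 1, 0)
      if (m > 0) {
        mask <- classify_edge_pixels(mats[[i]], edge_threshold)
        iv <- interp_interval(mats[[i]], mats[[i + 1]])
        prev <- if (i > 1) mats[[i - 1]] else NULL
        nxt <- if (i + 2 <= n) mats[[i + 2]] else NULL
        for (j in seq_len(m)) {
          w <- j / (m + 1)
          planes[[length(planes) + 1L]] <- interpolate_plane(iv, w, mask, prev, nxt)
          zs <- c(zs, z[i] + w * dz)
          prov <- c(prov, "interpolated")
          src <- c(src, NA_integer_)
        }
      }
    }
    planes[[length(planes) + 1L]] <- mats[[i + 1]]
    zs <- c(zs, z[i + 1])
    prov <- c(prov, "original")
    src <- c(src, i + 1L)
  }
  list(planes = planes, z = zs, provenance = prov, source_index = src)
}

#' Build the reconstruction volume
#'
#' Executes the full protocol on an ordered series: deduplicate overlapping
#' slices, fill gaps back to nominal sampling, then expand to `target_depth`
#' planes, synthesizing the extra planes at strictly interior fractional
#' positions `w_j = j/(m+1)` (anchor planes are never re-synthesized). Pixel
#' values of acquired planes are carried over bit-exactly.
#'
#' @param geometry Ordered `series_geometry` (classified or not).
#' @param plan Optional `build_plan`; its `n_files` must equal the plane
#'   count after deduplication and gap filling.
#' @param target_depth Requested output depth; default (`NULL`) keeps the
#'   post-gap-fill plane count (z step 1).
#' @param edge_threshold Gradient cutoff for the hybrid edge rule.
#' @param tolerance Spacing tolerance, mm.
#' @return A `volume_grid`: `voxels` array indexed (row, col, plane),
#'   physical spacings, origin, normal, per-plane `provenance` and `plane_z`.
#' @export
build_volume <- function(geometry, plan = NULL, target_depth = NULL,
                         edge_threshold = 100, tolerance = NULL) {
  stopifnot(inherits(geometry, "series_geometry"))
  if (length(geometry$slices) == 0)
    mpr_error("empty series: number of files is 0", "mpr_empty_series")
  if (is.null(geometry$interval_labels))
    geometry <- classify_intervals(geometry, tolerance)
  geometry <- select_slices_overlap(geometry, tolerance)
  filled <- fill_gaps(geometry, edge_threshold)
  n <- length(filled$planes)

  if (is.null(plan)) {
    td <- if (is.null(target_depth)) n else as.integer(target_depth)
    plan <- compute_z_step(n, td)
  } else {
    if (!inherits(plan, "build_plan") || plan$n_files != n)
      mpr_error(sprintf(
        "plan/geometry mismatch: plan expects %d planes, series provides %d after gap filling",
        plan$n_files, n), "mpr_parameter_error")
  }

  first <- geometry$slices[[1]]
  nr <- first$rows; nc <- first$cols
  depth <- plan$target_depth
  vox <- array(0, dim = c(nr, nc, depth))
  prov <- character(depth)
  plane_z <- numeric(depth)

  p <- 1L
  put <- function(mat, z, tag) {
    vox[, , p] <<- mat
    prov[p] <<- tag
    plane_z[p] <<- z
    p <<- p + 1L
  }
  put(filled$planes[[1]], filled$z[1], filled$provenance[1])
  for (i in seq_len(n - 1)) {
    m <- plan$planes_per_interval[i]
    if (m > 0) {
      mask <- classify_edge_pixels(filled$planes[[i]], edge_threshold)
      iv <- interp_interval(filled$planes[[i]], filled$planes[[i + 1]])
      prev <- if (i > 1) filled$planes[[i - 1]] else NULL
      nxt <- if (i + 2 <= n) filled$planes[[i + 2]] else NULL
      dz <- filled$z[i + 1] - filled$z[i]
      for (j in seq_len(m)) {
        w <- j / (m + 1)
        put(interpolate_plane(iv, w, mask, prev, nxt),
            filled$z[i] + w * dz, "interpolated")
      }
    }
    put(filled$planes[[i + 1]], filled$z[i + 1], filled$provenance[i + 1])
  }

  extent <- filled$z[n] - filled$z[1]
  spacing_plane <- if (depth > 1) extent / (depth - 1) else first$slice_thickness
  structure(list(
    voxels = vox,
    spacing_row = first$pixel_spacing_row,
    spacing_col = first$pixel_spacing_col,
    spacing_plane = spacing_plane,
    origin = if (is.null(first$image_position)) c(0, 0, 0) else first$image_position,
    normal = geometry$normal,
    provenance = prov,
    plane_z = plane_z,
    z_step = plan$z_step,
    window_center = first$window_center,
    window_width = first$window_width,
    rescale_slope = first$rescale_slope,
    rescale_intercept = first$rescale_intercept
  ), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volume_grid %dx%dx%d, spacing %.4gx%.4gx%.4g mm, %d original / %d interpolated planes>\n",
              d[1], d[2], d[3], x$spacing_row, x$spacing_col, x$spacing_plane,
              sum(x$provenance == "original"), sum(x$provenance == "interpolated")))
  invisible(x)
}

#' Export a volume as raw float32 + JSON sidecar
#'
#' Writes `<prefix>.raw` (little-endian float32, plane-major: plane, then
#' row-major pixels within each plane) and `<prefix>.json` describing
#' dimensions, spacings, origin, normal, and per-plane provenance.
#'
#' @param volume A `volume_grid`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_volume_raw <- function(volume, prefix) {
  d <- dim(volume$voxels)
  raw_path <- paste0(prefix, ".raw")
  con <- file(raw_path, "wb")
  # plane-major, row-major within plane
  for (pl in seq_len(d[3]))
    writeBin(as.numeric(t(volume$voxels[, , pl])), con, size = 4, endian = "little")
  close(con)
  sidecar <- list(
    dims = d,
    spacing_mm = list(row = volume$spacing_row, col = volume$spacing_col,
                      plane = volume$spacing_plane),
    origin_mm = volume$origin,
    normal = volume$normal,
    z_step = volume$z_step,
    plane_provenance = volume$provenance,
    plane_z_mm = volume$plane_z,
    index_base = 1,
    layout = "plane-major; within a plane rows are stored top to bottom, row-major"
  )
  json_path <- paste0(prefix, ".json")
  jsonlite::write_json(sidecar, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(raw_path, json_path))
}

#' Convert volume planes back to a DICOM-ready slice list
#'
#' Voxels are rounded half-even to integers at export, per the viewer
#' pipeline where interpolation runs on stored values.
#'
#' @param volume A `volume_grid`.
#' @return List of [slice_record()]s, one per plane.
#' @export
volume_to_slices <- function(volume) {
  d <- dim(volume$voxels)
  lapply(seq_len(d[3]), function(pl) {
    m <- round(volume$voxels[, , pl])
    storage.mode(m) <- "integer"
    slice_record(
      pixel_matrix = m,
      image_position = volume$origin + volume$normal * (volume$plane_z[pl] - volume$plane_z[1]),
      orientation = c(1, 0, 0, 0, 1, 0),
      pixel_spacing = c(volume$spacing_row, volume$spacing_col),
      slice_thickness = volume$spacing_plane,
      spacing_between_slices = volume$spacing_plane,
      instance_number = pl,
      rescale_slope = volume$rescale_slope,
      rescale_intercept = volume$rescale_intercept,
      window_center = volume$window_center,
      window_width = volume$window_width
    )
  })
}
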