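# Ordering slices along the scan axis, classifying inter-slice intervals
# (contiguous / gap / overlap), and computing the z-step build plan.

#' Slice normal from orientation cosines
#'
#' Cross product of the row-axis and column-axis direction cosines, normalized.
#' For the canonical axial orientation (1,0,0, 0,1,0) this is (0,0,1).
#'
#' @param orientation Numeric length-6: row-axis xyz then column-axis xyz.
#' @return Unit 3-vector normal to the slice plane.
#' @export
slice_normal <- function(orientation) {
  if (length(orientation) != 6)
    mpr_error("orientation must hold 6 direction cosines", "mpr_geometry_error")
  r <- orientation[1:3]; cc <- orientation[4:6]
  n <- c(r[2] * cc[3] - r[3] * cc[2],
         r[3] * cc[1] - r[1] * cc[3],
         r[1] * cc[2] - r[2] * cc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-6)
    mpr_error("degenerate orientation: row and column axes are parallel", "mpr_geometry_error")
  n / nn
}

# nominal z sampling unit for a series. Slice thickness (the acquired slab
# width) is the natural unit: thinner slices than their spacing mean physical
# gaps, thicker mean overlap. Fallbacks cover series with the thickness tag
# missing and series whose spacing tag is 0 (seen in the wild).
.nominal_spacing <- function(slices, z) {
  th <- slices[[1]]$slice_thickness
  if (!is.null(th) && is.finite(th) && th > 0) return(th)
  sb <- slices[[1]]$spacing_between_slices
  if (!is.null(sb) && is.finite(sb) && sb > 0) return(sb)
  dz <- diff(z)
  dz <- dz[is.finite(dz) & dz > 0]
  if (length(dz) > 0) return(stats::median(dz))
  mpr_error("cannot determine nominal slice spacing", "mpr_geometry_error")
}

#' Order a series along the scan axis
#'
#' Sorts slices by ascending signed distance along the slice normal
#' (projection of Image Position (Patient) onto the normal), breaking ties by
#' ascending instance number, then by slice location. When image positions are
#' absent the chain falls back to instance number, then slice location.
#'
#' @param slices List of [slice_record()]s (>= 2, consistent orientation).
#' @return A `series_geometry`: the ordered slices plus `normal`,
#'   `z_positions`, `nominal_spacing`, and (after
#'   [classify_intervals()]) `interval_labels`.
#' @export
order_slices <- function(slices) {
  if (length(slices) < 2)
    mpr_error("insufficient series: need at least 2 slices", "mpr_insufficient")
  normals <- vapply(slices, function(s) slice_normal(s$orientation), numeric(3))
  n0 <- normals[, 1]
  dev <- apply(normals, 2, function(v) max(abs(v - n0)))
  if (any(dev > 1e-3))
    mpr_error("mixed orientation: slice normals disagree", "mpr_inconsistent")

  has_pos <- vapply(slices, function(s) !is.null(s$image_position), logical(1))
  inst <- vapply(slices, function(s)
    if (is.null(s$instance_number)) NA_real_ else as.numeric(s$instance_number), numeric(1))
  loc <- vapply(slices, function(s)
    if (is.null(s$slice_location)) NA_real_ else s$slice_location, numeric(1))

  if (all(has_pos)) {
    z <- vapply(slices, function(s) sum(s$image_position * n0), numeric(1))
    ord <- order(z, inst, loc, na.last = TRUE)
  } else {
    # fallback chain: instance number, then slice location
    ord <- order(inst, loc, na.last = TRUE)
    z <- rep(NA_real_, length(slices))
  }
  slices <- slices[ord]
  z <- z[ord]
  if (any(is.na(z))) {
    # derive usable z positions for downstream stages
    locs <- loc[ord]
    if (!anyNA(locs) && !is.unsorted(locs)) z <- locs
  }
  geom <- structure(list(
    slices = slices,
    normal = n0,
    z_positions = z,
    nominal_spacing = NA_real_,
    interval_labels = NULL
  ), class = "series_geometry")
  if (any(is.na(geom$z_positions))) {
    ns <- .nominal_spacing(slices, geom$z_positions)
    geom$z_positions <- (seq_along(slices) - 1) * ns
  }
  geom$nominal_spacing <- .nominal_spacing(slices, geom$z_positions)
  geom
}

#' @export
print.series_geometry <- function(x, ...) {
  cat(sprintf("<series_geometry %d slices, nominal spacing %g mm", length(x$slices), x$nominal_spacing))
  if (!is.null(x$interval_labels))
    cat(sprintf("; intervals: %s", paste(names(table(x$interval_labels)),
                                         table(x$interval_labels), collapse = " ", sep = "=")))
  cat(">\n")
  invisible(x)
}

#' Default interval-classification tolerance
#'
#' One percent of the nominal spacing, floored at 0.01 mm: wide enough to
#' absorb floating-point noise in scanner metadata without masking real gaps.
#'
#' @param nominal_spacing Nominal slice spacing, mm.
#' @return Tolerance in mm.
#' @export
default_spacing_tol <- function(nominal_spacing) {
  max(0.01 * nominal_spacing, 0.01)
}

#' Classify inter-slice intervals
#'
#' Labels each interval between consecutive ordered slices: `contiguous` when
#' the observed step matches the nominal spacing within tolerance, `gap` when
#' it is larger, `overlap` when smaller (including duplicated positions).
#'
#' @param geometry An ordered `series_geometry` from [order_slices()].
#' @param tolerance Acceptance band in mm; defaults to
#'   [default_spacing_tol()].
#' @return The geometry with `interval_labels` filled in (character vector of
#'   length `n_slices - 1`).
#' @export
classify_intervals <- function(geometry, tolerance = NULL) {
  stopifnot(inherits(geometry, "series_geometry"))
  dz <- diff(geometry$z_positions)
  if (any(dz < 0))
    mpr_error("internal invariant violation: decreasing z after ordering", "mpr_geometry_error")
  ns <- geometry$nominal_spacing
  if (is.null(tolerance)) tolerance <- default_spacing_tol(ns)
  labels <- ifelse(abs(dz - ns) <= tolerance, "contiguous",
                   ifelse(dz > ns + tolerance, "gap", "overlap"))
  geometry$interval_labels <- labels
  geometry
}

#' Compute the z step and plane budget for volume building
#'
#' The z step is the expansion factor from acquired slice count to the
#' requested volume depth. When the counts match the step is 1 and no planes
#' are synthesized. Otherwise `round(z_step) - 1` planes are budgeted per
#' interval, with the remainder pushed onto the trailing intervals so the
#' total output depth equals `target_depth` exactly.
#'
#' @param n_files Number of input slices (planes) available.
#' @param target_depth Requested z-dimension of the output volume
#'   (`>= n_files`).
#' @return A `build_plan` with `z_step`, `target_depth`, and
#'   `planes_per_interval` (length `n_files - 1`).
#' @export
compute_z_step <- function(n_files, target_depth) {
  if (n_files == 0)
    mpr_error("empty series: number of files is 0", "mpr_empty_series")
  if (target_depth < 1)
    mpr_error("target depth must be >= 1", "mpr_parameter_error")
  if (target_depth < n_files)
    mpr_error("target depth smaller than slice count is not supported", "mpr_parameter_error")
  if (n_files == target_depth) {
    plan <- list(z_step = 1, target_depth = as.integer(target_depth),
                 n_files = as.integer(n_files),
                 planes_per_interval = rep(0L, max(n_files - 1, 0)))
    return(structure(plan, class = "build_plan"))
  }
  z_step <- target_depth / n_files
  m <- max(round(z_step) - 1, 0)
  planes <- rep(as.integer(m), n_files - 1)
  rem <- target_depth - n_files - sum(planes)
  i <- n_files - 1
  planes[i] <- planes[i] + as.integer(rem)
  while (i > 1 && planes[i] < 0) {        # cascade when round() overshoots
    planes[i - 1] <- planes[i - 1] + planes[i]
    planes[i] <- 0L
    i <- i - 1
  }
  if (any(planes < 0))
    mpr_error("internal invariant violation: negative plane budget", "mpr_geometry_error")
  structure(list(z_step = z_step, target_depth = as.integer(target_depth),
                 n_files = as.integer(n_files),
                 planes_per_interval = planes),
            class = "build_plan")
}

#' @export
print.build_plan <- function(x, ...) {
  cat(sprintf("<build_plan z_step=%.4g, %d files -> depth %d>\n",
              x$z_step, x$n_files, x$target_depth))
  invisible(x)
}
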