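# Viewer measurement tools (length, angle, probe, ROI statistics) and the
# validation machinery: half-maximum sub-pixel edge localization and the
# mean-absolute-error statistic used to compare measurements across views.
#
# All tools take (row, col) pixel coordinates and report millimetres (or HU
# for the probe); conversion to physical units always goes through the view's
# per-axis spacings.

#' Distance between two points in millimetres
#'
#' @param p1,p2 Length-2 `(row, col)` pixel coordinates (may be fractional).
#' @param spacing_h Column (horizontal) spacing, mm/pixel.
#' @param spacing_v Row (vertical) spacing, mm/pixel.
#' @return Euclidean distance in mm.
#' @export
measure_length <- function(p1, p2, spacing_h = 1, spacing_v = 1) {
  if (spacing_h <= 0 || spacing_v <= 0)
    mpr_error("spacings must be positive", "mpr_parameter_error")
  sqrt(((p2[2] - p1[2]) * spacing_h)^2 + ((p2[1] - p1[1]) * spacing_v)^2)
}

#' Interior angle at a vertex, in degrees
#'
#' Computed in physical (mm) coordinates so anisotropic pixels do not distort
#' the angle.
#'
#' @param p1,vertex,p2 Length-2 `(row, col)` pixel coordinates.
#' @inheritParams measure_length
#' @return Angle in `[0, 180]` degrees.
#' @export
measure_angle <- function(p1, vertex, p2, spacing_h = 1, spacing_v = 1) {
  to_mm <- function(p) c((p[1] - vertex[1]) * spacing_v, (p[2] - vertex[2]) * spacing_h)
  a <- to_mm(p1); b <- to_mm(p2)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    mpr_error("degenerate geometry: arm coincides with the vertex", "mpr_parameter_error")
  cosang <- sum(a * b) / (na * nb)
  cosang <- min(max(cosang, -1), 1)
  acos(cosang) * 180 / pi
}

#' Probe: Hounsfield value at a point
#'
#' Reads the stored value at the nearest pixel and applies the slice's
#' modality rescale.
#'
#' @param slice A [slice_record()].
#' @param p Length-2 `(row, col)` point (fractional coordinates are rounded
#'   to the nearest pixel).
#' @return HU value.
#' @export
probe <- function(slice, p) {
  r <- round(p[1]); c_ <- round(p[2])
  if (r < 1 || r > slice$rows || c_ < 1 || c_ > slice$cols)
    mpr_error("probe point lies outside the image", "mpr_bounds_error")
  apply_rescale(slice$pixel_matrix[r, c_], slice$rescale_slope, slice$rescale_intercept)
}

#' Define a region of interest
#'
#' Rectangles and ellipses are given by two corner points of their bounding
#' box; freehand ROIs by at least three vertices of a simple polygon.
#' Coordinates are `(row, col)` pixels.
#'
#' @param kind `"rectangle"`, `"ellipse"`, or `"freehand"`.
#' @param points Numeric matrix with one `(row, col)` point per row.
#' @return A `roi_shape` object.
#' @export
roi_shape <- function(kind = c("rectangle", "ellipse", "freehand"), points) {
  kind <- match.arg(kind)
  points <- matrix(as.numeric(points), ncol = 2)
  need <- if (kind == "freehand") 3 else 2
  if (nrow(points) < need)
    mpr_error(sprintf("%s ROI needs at least %d points", kind, need), "mpr_parameter_error")
  structure(list(kind = kind, points = points), class = "roi_shape")
}

# logical membership matrix: pixel centres (integer coordinates) inside shape
.roi_mask <- function(image, roi) {
  nr <- nrow(image); nc <- ncol(image)
  rr <- matrix(rep(seq_len(nr), nc), nr, nc)
  cc <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  p <- roi$points
  switch(roi$kind,
    rectangle = {
      rmin <- min(p[, 1]); rmax <- max(p[, 1])
      cmin <- min(p[, 2]); cmax <- max(p[, 2])
      rr >= rmin & rr <= rmax & cc >= cmin & cc <= cmax
    },
    ellipse = {
      cr <- mean(range(p[, 1])); ccen <- mean(range(p[, 2]))
      ar <- diff(range(p[, 1])) / 2; ac <- diff(range(p[, 2])) / 2
      if (ar <= 0 || ac <= 0) return(matrix(FALSE, nr, nc))
      ((rr - cr) / ar)^2 + ((cc - ccen) / ac)^2 <= 1
    },
    freehand = {
      inside <- pracma::inpolygon(as.numeric(cc), as.numeric(rr),
                                  p[, 2], p[, 1], boundary = TRUE)
      matrix(inside, nr, nc)
    }
  )
}

#' ROI statistics
#'
#' Statistics over the pixels whose centres fall inside the shape; the area
#' is `pixel_count * spacing_h * spacing_v`.
#'
#' @param image Numeric matrix (stored values or HU).
#' @param roi A [roi_shape()].
#' @inheritParams measure_length
#' @return List: `mean`, `sd`, `min`, `max`, `area_mm2`, `pixel_count`.
#' @export
roi_stats <- function(image, roi, spacing_h = 1, spacing_v = 1) {
  mask <- .roi_mask(image, roi)
  vals <- image[mask]
  if (length(vals) == 0)
    mpr_error("empty ROI: no pixel centres inside the shape", "mpr_not_found")
  list(
    mean = mean(vals),
    sd = if (length(vals) > 1) stats::sd(vals) else 0,
    min = min(vals),
    max = max(vals),
    area_mm2 = length(vals) * spacing_h * spacing_v,
    pixel_count = length(vals)
  )
}

#' Mean absolute error between measured and ground-truth values
#'
#' The validation statistic: `error = (1/n) * sum(|M_i - G_i|)`, with
#' measured values `M` (e.g. lengths read off reconstructed coronal/sagittal
#' views) and ground truth `G` (the same structure measured on the axial
#' source view).
#'
#' @param measured,ground_truth Equal-length numeric vectors, mm.
#' @return A `measurement_set`: `measured`, `ground_truth`, `n`, `error`.
#' @export
error_margin <- function(measured, ground_truth) {
  if (length(measured) != length(ground_truth) || length(measured) == 0)
    mpr_error("measured and ground-truth vectors must have equal non-zero length",
              "mpr_parameter_error")
  structure(list(
    measured = as.numeric(measured),
    ground_truth = as.numeric(ground_truth),
    n = length(measured),
    error = mean(abs(measured - ground_truth))
  ), class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf("<measurement_set n=%d, mean abs error %.6g mm>\n", x$n, x$error))
  invisible(x)
}

#' Sub-pixel edge positions along an intensity profile
#'
#' Edges are located where the profile crosses its half-maximum level,
#' `(min + max)/2`, with linear interpolation between samples — an automated
#' stand-in for manually clicking the visible edge of a high-contrast
#' structure. Positions are millimetres from the first sample centre.
#'
#' @param profile Numeric vector (length >= 2).
#' @param spacing Sample spacing, mm.
#' @return Numeric vector of edge positions (mm), in profile order.
#' @export
locate_edges_subpixel <- function(profile, spacing = 1) {
  n <- length(profile)
  if (n < 2)
    mpr_error("profile must contain at least 2 samples", "mpr_parameter_error")
  lo <- min(profile); hi <- max(profile)
  if (hi == lo)
    mpr_error("no edges: profile is flat", "mpr_not_found")
  level <- (lo + hi) / 2
  pos <- numeric(0)
  for (i in seq_len(n - 1)) {
    a <- profile[i]; b <- profile[i + 1]
    if (a == b) next
    crosses <- (a < level && b >= level) || (a > level && b <= level)
    if (crosses)
      pos <- c(pos, (i - 1 + (level - a) / (b - a)) * spacing)
  }
  if (length(pos) == 0)
    mpr_error("no edges: profile never crosses its half-maximum", "mpr_not_found")
  pos
}

#' Measure a structure's extent along a view line
#'
#' Extracts the intensity profile along one row (`axis = "h"`) or column
#' (`axis = "v"`) of a view, localizes its half-maximum edges, and returns
#' the distance between the first and last edge in millimetres.
#'
#' @param view A `view_image` from [extract_plane()].
#' @param axis `"h"` (profile along a row, using `spacing_h`) or `"v"`
#'   (profile along a column, using `spacing_v`).
#' @param line_index 1-based row (for `"h"`) or column (for `"v"`) index.
#' @return Extent in mm.
#' @export
measure_extent <- function(view, axis = c("h", "v"), line_index) {
  axis <- match.arg(axis)
  px <- view$pixels
  if (axis == "h") {
    if (line_index < 1 || line_index > nrow(px))
      mpr_error("line index out of range", "mpr_bounds_error")
    profile <- px[line_index, ]
    spacing <- view$spacing_h
  } else {
    if (line_index < 1 || line_index > ncol(px))
      mpr_error("line index out of range", "mpr_bounds_error")
    profile <- px[, line_index]
    spacing <- view$spacing_v
  }
  edges <- tryCatch(locate_edges_subpixel(profile, spacing),
                    mpr_not_found = function(e) numeric(0))
  if (length(edges) < 2)
    mpr_error("structure not found: fewer than 2 half-maximum crossings",
              "mpr_not_found")
  max(edges) - min(edges)
}
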