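# Orthogonal view extraction, cross-view reference lines, and display
# transforms (window/level, invert, magnify).
#
# View conventions (1-based indices throughout):
#   axial    fixes the plane axis; view pixels = (row, col)
#   coronal  fixes the volume row;  view pixels = (plane, col)
#   sagittal fixes the volume col;  view pixels = (plane, row)
# Views are exported unresampled; physical aspect is carried by the per-axis
# spacings (spacing_v for view rows, spacing_h for view columns).

.PLANE_KINDS <- c("axial", "coronal", "sagittal")

#' Extract an orthogonal view from a volume
#'
#' No resampling is performed: the anisotropic pixel is described by
#' `spacing_v` (view rows) and `spacing_h` (view columns), keeping
#' millimetre measurements exact.
#'
#' @param volume A `volume_grid`.
#' @param plane_kind `"axial"`, `"coronal"`, or `"sagittal"`.
#' @param index 1-based position along the fixed axis.
#' @return A `view_image`: `pixels`, `spacing_h`, `spacing_v`, `plane_kind`,
#'   `index`.
#' @export
extract_plane <- function(volume, plane_kind = c("axial", "coronal", "sagittal"), index) {
  plane_kind <- match.arg(plane_kind)
  d <- dim(volume$voxels)
  limit <- switch(plane_kind, axial = d[3], coronal = d[1], sagittal = d[2])
  if (index < 1 || index > limit)
    mpr_error(sprintf("%s index %d out of range [1, %d]", plane_kind, index, limit),
              "mpr_bounds_error")
  px <- switch(plane_kind,
    axial    = volume$voxels[, , index],
    coronal  = t(matrix(volume$voxels[index, , ], nrow = d[2])),   # (plane, col)
    sagittal = t(matrix(volume$voxels[, index, ], nrow = d[1]))    # (plane, row)
  )
  sp <- switch(plane_kind,
    axial    = c(h = volume$spacing_col, v = volume$spacing_row),
    coronal  = c(h = volume$spacing_col, v = volume$spacing_plane),
    sagittal = c(h = volume$spacing_row, v = volume$spacing_plane)
  )
  structure(list(
    pixels = px,
    spacing_h = unname(sp["h"]),
    spacing_v = unname(sp["v"]),
    plane_kind = plane_kind,
    index = as.integer(index)
  ), class = "view_image")
}

#' @export
print.view_image <- function(x, ...) {
  cat(sprintf("<view_image %s #%d, %dx%d px, %.4g x %.4g mm/px>\n",
              x$plane_kind, x$index, nrow(x$pixels), ncol(x$pixels),
              x$spacing_v, x$spacing_h))
  invisible(x)
}

#' Cross-view reference line
#'
#' The intersection of the source plane with the target view, expressed as a
#' segment in target-view pixel coordinates (1-based `(row, col)` endpoints).
#' E.g. coronal plane `r` appears on an axial view as the horizontal line at
#' row `r`.
#'
#' @param volume A `volume_grid`.
#' @param source_kind,source_index Plane being projected.
#' @param target_kind View the line is drawn on (different kind).
#' @return A `reference_line`: `view`, `endpoints` (2x2 matrix, rows =
#'   endpoints), `source`.
#' @export
reference_line <- function(volume, source_kind, source_index, target_kind) {
  source_kind <- match.arg(source_kind, .PLANE_KINDS)
  target_kind <- match.arg(target_kind, .PLANE_KINDS)
  if (source_kind == target_kind)
    mpr_error("parallel planes do not intersect", "mpr_geometry_error")
  d <- dim(volume$voxels)  # (rows, cols, planes)
  tv_dims <- switch(target_kind,   # (view rows, view cols)
    axial = c(d[1], d[2]), coronal = c(d[3], d[2]), sagittal = c(d[3], d[1]))

  # orientation of the source plane on the target view and the fixed
  # coordinate: horizontal line at view row r, or vertical line at view col c
  key <- paste(source_kind, target_kind, sep = "->")
  pos <- source_index
  horiz <- switch(key,
    "coronal->axial"    = TRUE,   # volume row r -> axial row r
    "sagittal->axial"   = FALSE,  # volume col c -> axial col c
    "axial->coronal"    = TRUE,   # plane p -> coronal row p
    "sagittal->coronal" = FALSE,  # volume col c -> coronal col c
    "axial->sagittal"   = TRUE,   # plane p -> sagittal row p
    "coronal->sagittal" = FALSE   # volume row r -> sagittal col r
  )
  endpoints <- if (horiz) {
    rbind(c(pos, 1), c(pos, tv_dims[2]))
  } else {
    rbind(c(1, pos), c(tv_dims[1], pos))
  }
  structure(list(
    view = target_kind,
    endpoints = endpoints,
    source = list(plane_kind = source_kind, index = as.integer(source_index))
  ), class = "reference_line")
}

#' Linear window/level display transform
#'
#' Maps intensities to the 8-bit display range: values at or below
#' `center - width/2` render black, at or above `center + width/2` white,
#' linear in between; rounding is half-even.
#'
#' @param image Numeric matrix (HU or stored units — match `center`/`width`).
#' @param center,width Window centre and width (`width >= 1`).
#' @return Integer matrix in `[0, 255]`.
#' @export
apply_window <- function(image, center, width) {
  if (width < 1)
    mpr_error("window width must be >= 1", "mpr_parameter_error")
  lo <- center - width / 2
  out <- (image - lo) / width * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  m <- round(out)
  storage.mode(m) <- "integer"
  m
}

#' Invert an 8-bit display image
#'
#' @param display Matrix with values in `[0, 255]`.
#' @return `255 - display`.
#' @export
invert_display <- function(display) {
  if (any(display < 0) || any(display > 255))
    mpr_error("display values must lie in [0, 255]", "mpr_parameter_error")
  if (is.integer(display)) 255L - display else 255 - display
}

# continuous bicubic sample at (r, c) (1-based, fractional) with replicate
# clamping at the image border
.bicubic_sample <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  fr <- floor(r); fc <- floor(c)
  fr <- min(max(fr, 1), nr); fc <- min(max(fc, 1), nc)
  u <- r - fr; v <- c - fc
  ri <- pmin(pmax(fr + (-1:2), 1), nr)
  ci <- pmin(pmax(fc + (-1:2), 1), nc)
  bicubic_eval(image[ri, ci], u, v)
}

#' Magnified crop of an image
#'
#' Crops a window of `output_size / factor` pixels around `center` and
#' resamples it to `output_size` with bicubic (Catmull-Rom) interpolation —
#' the computational kernel behind a viewer's magnify/zoom tools.
#'
#' @param image Numeric matrix.
#' @param center Length-2 `(row, col)` centre of the magnified region
#'   (1-based, may be fractional).
#' @param factor Magnification factor (`>= 1`).
#' @param output_size Length-2 `(rows, cols)` of the output (defaults to the
#'   input size).
#' @return Numeric matrix of `output_size`.
#' @export
magnify <- function(image, center, factor = 2, output_size = dim(image)) {
  if (factor < 1)
    mpr_error("magnification factor must be >= 1", "mpr_parameter_error")
  if (center[1] < 1 || center[1] > nrow(image) ||
      center[2] < 1 || center[2] > ncol(image))
    mpr_error("magnification centre lies outside the image", "mpr_bounds_error")
  out_r <- output_size[1]; out_c <- output_size[2]
  # source coordinates: output pixel i maps to center + (i - (n+1)/2)/factor
  src_r <- center[1] + (seq_len(out_r) - (out_r + 1) / 2) / factor
  src_c <- center[2] + (seq_len(out_c) - (out_c + 1) / 2) / factor
  out <- matrix(0, out_r, out_c)
  for (i in seq_len(out_r))
    for (j in seq_len(out_c))
      out[i, j] <- .bicubic_sample(image, src_r[i], src_c[j])
  out
}

#' Write a view image as an 8-bit grayscale PNG
#'
#' Applies the window/level transform then writes PNG (requires the `png`
#' package). A JSON sidecar records spacings and plane metadata.
#'
#' @param view A `view_image`.
#' @param path Output PNG path.
#' @param center,width Display window (defaults: full data range).
#' @param invert Invert the grayscale ramp.
#' @return Invisibly, `path`.
#' @export
write_view_png <- function(view, path, center = NULL, width = NULL, invert = FALSE) {
  if (!requireNamespace("png", quietly = TRUE))
    mpr_error("the 'png' package is required for PNG export", "mpr_io_error")
  px <- view$pixels
  if (is.null(center)) center <- (max(px) + min(px)) / 2
  if (is.null(width)) width <- max(max(px) - min(px), 1)
  disp <- apply_window(px, center, width)
  if (invert) disp <- invert_display(disp)
  png::writePNG(disp / 255, path)
  sidecar <- list(plane_kind = view$plane_kind, index = view$index,
                  spacing_h_mm = view$spacing_h, spacing_v_mm = view$spacing_v,
                  window_center = center, window_width = width,
                  index_base = 1)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
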