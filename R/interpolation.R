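# Hybrid inter-slice interpolation kernels.
#
# A synthesized plane between two acquired planes V_i and V_{i+1} at
# fractional position w in (0,1) is assembled pixel-by-pixel:
#   * non-edge interior pixels: weighted bilinear average over the pixel and
#     its two lateral neighbours in both anchor planes,
#       P(k) = (1-w)(0.5 V_i[k] + 0.25 V_i[k-1] + 0.25 V_i[k+1])
#            +    w (0.5 V_{i+1}[k] + 0.25 V_{i+1}[k-1] + 0.25 V_{i+1}[k+1])
#   * array-boundary pixels (one lateral neighbour): weights become 0.75 for
#     the pixel itself and 0.25 for the available neighbour, scaled by the
#     same (1-w)/w split,
#   * intensity-edge pixels (gradient magnitude above a threshold): cubic
#     convolution (Catmull-Rom, a = -0.5) along z, which preserves sharp
#     transitions better than lateral averaging.
#
# The lateral neighbour axis is the flattened row-major pixel index, so k-1 /
# k+1 are horizontal (column) neighbours; first- and last-column pixels are
# treated as boundary pixels so no neighbourhood wraps across rows.

#' Pair of anchor planes for inter-slice interpolation
#'
#' @param plane_current,plane_next Numeric matrices of identical shape: the
#'   acquired planes bracketing the synthesized position.
#' @param weights Fractional positions in (0,1), one per plane to synthesize.
#' @return An `interp_interval` object.
#' @export
interp_interval <- function(plane_current, plane_next, weights = numeric(0)) {
  if (!all(dim(plane_current) == dim(plane_next)))
    mpr_error("anchor planes must have identical shape", "mpr_parameter_error")
  if (length(weights) && (any(weights <= 0) || any(weights >= 1)))
    mpr_error("interpolation weights must lie strictly in (0,1)", "mpr_parameter_error")
  structure(list(
    plane_current = plane_current,
    plane_next = plane_next,
    weights = weights,
    length = length(plane_current)
  ), class = "interp_interval")
}

# flattened row-major index -> (row, col); k is 1-based here
.k_to_rc <- function(k, ncol) {
  r <- (k - 1) %/% ncol + 1
  c(r, k - (r - 1) * ncol)
}

#' Weighted bilinear interpolation for a non-edge pixel
#'
#' @param interval An [interp_interval()].
#' @param k 1-based flattened row-major pixel index; must have both lateral
#'   neighbours within the same row.
#' @param w Fractional position in `[0, 1]`.
#' @return Interpolated value.
#' @export
interp_nonedge <- function(interval, k, w) {
  nc <- ncol(interval$plane_current)
  rc <- .k_to_rc(k, nc)
  if (rc[2] <= 1 || rc[2] >= nc)
    mpr_error("pixel is at the array boundary; use interp_boundary", "mpr_parameter_error")
  vi <- t(interval$plane_current)[c(k - 1, k, k + 1)]
  vn <- t(interval$plane_next)[c(k - 1, k, k + 1)]
  (1 - w) * (0.5 * vi[2] + 0.25 * vi[1] + 0.25 * vi[3]) +
    w * (0.5 * vn[2] + 0.25 * vn[1] + 0.25 * vn[3])
}

#' Weighted interpolation for an array-boundary pixel
#'
#' At the first/last pixel of a row only one lateral neighbour exists; the
#' weights become 0.75 (pixel) and 0.25 (available neighbour), scaled by the
#' same `(1-w)` / `w` split as the interior rule. A degenerate single-pixel
#' row reduces to the plain linear blend.
#'
#' @inheritParams interp_nonedge
#' @return Interpolated value.
#' @export
interp_boundary <- function(interval, k, w) {
  nc <- ncol(interval$plane_current)
  rc <- .k_to_rc(k, nc)
  vi <- t(interval$plane_current); vn <- t(interval$plane_next)
  if (nc == 1)
    return((1 - w) * vi[k] + w * vn[k])
  kp <- if (rc[2] == 1) k + 1 else k - 1  # the single available neighbour
  if (rc[2] != 1 && rc[2] != nc)
    mpr_error("pixel is interior; use interp_nonedge", "mpr_parameter_error")
  (1 - w) * (0.75 * vi[k] + 0.25 * vi[kp]) +
    w * (0.75 * vn[k] + 0.25 * vn[kp])
}

#' Flag intensity-edge pixels
#'
#' Central-difference gradient magnitude above `threshold` marks a pixel as an
#' intensity edge; edge pixels are interpolated with the cubic (bicubic)
#' kernel rather than lateral averaging. Image-border pixels are never
#' flagged (no full 4x4 support).
#'
#' @param plane Numeric matrix.
#' @param threshold Gradient-magnitude cutoff in stored-value units
#'   (default 100).
#' @return Logical matrix of the same shape (`TRUE` = edge pixel).
#' @export
classify_edge_pixels <- function(plane, threshold = 100) {
  nr <- nrow(plane); nc <- ncol(plane)
  mask <- matrix(FALSE, nr, nc)
  if (nr < 3 || nc < 3 || !is.finite(threshold)) return(mask)
  gx <- (plane[2:(nr - 1), 3:nc] - plane[2:(nr - 1), 1:(nc - 2)]) / 2
  gy <- (plane[3:nr, 2:(nc - 1)] - plane[1:(nr - 2), 2:(nc - 1)]) / 2
  mask[2:(nr - 1), 2:(nc - 1)] <- sqrt(gx^2 + gy^2) > threshold
  mask
}

## ---- cubic convolution (Catmull-Rom, a = -0.5) ------------------------------

# Catmull-Rom basis matrix: f(t) = [1 t t^2 t^3] %*% .CR_M %*% c(P0,P1,P2,P3)
.CR_M <- 0.5 * matrix(c(
   0,  2,  0,  0,
  -1,  0,  1,  0,
   2, -5,  4, -1,
  -1,  3, -3,  1
), nrow = 4, byrow = TRUE)

# 1D Catmull-Rom through knots p0..p3 at t in [0,1] between p1 and p2;
# vectorized over matrices/vectors of knot values
.cubic_cr <- function(p0, p1, p2, p3, t) {
  0.5 * ((2 * p1) +
         (-p0 + p2) * t +
         (2 * p0 - 5 * p1 + 4 * p2 - p3) * t^2 +
         (-p0 + 3 * p1 - 3 * p2 + p3) * t^3)
}

#' Polynomial coefficients of a bicubic patch
#'
#' Returns the 4x4 coefficient matrix `a` such that the patch value at
#' `(u, v)` is `sum a[i+1, j+1] u^i v^j`, for the Catmull-Rom (a = -0.5)
#' cubic-convolution kernel. `u` runs along the grid rows, `v` along the
#' columns; `(u, v) = (0, 0)` is the second-row/second-column knot.
#'
#' @param grid Numeric 4x4 matrix of data points.
#' @return 4x4 coefficient matrix.
#' @export
bicubic_coefficients <- function(grid) {
  if (!all(dim(grid) == c(4, 4)))
    mpr_error("bicubic patch requires a 4x4 grid", "mpr_parameter_error")
  .CR_M %*% grid %*% t(.CR_M)
}

#' Evaluate bicubic interpolation on a 4x4 patch
#'
#' Separable cubic convolution with the Catmull-Rom kernel: smooth (C^1),
#' reproduces constants and linear ramps exactly, and interpolates its knots
#' (`u = v = 0` returns `grid[2, 2]`).
#'
#' @param grid Numeric 4x4 matrix.
#' @param u,v Interpolation parameters in `[0, 1]`.
#' @return Interpolated scalar.
#' @export
bicubic_eval <- function(grid, u, v) {
  if (u < 0 || u > 1 || v < 0 || v > 1)
    mpr_error("interpolation parameters must lie in [0, 1]", "mpr_parameter_error")
  a <- bicubic_coefficients(grid)
  uu <- c(1, u, u^2, u^3); vv <- c(1, v, v^2, v^3)
  as.numeric(t(uu) %*% a %*% vv)
}

## ---- whole-plane interpolation ----------------------------------------------

# cubic interpolation along z for every pixel at once; anchor planes outside
# the interval are replicate-clamped when unavailable
.interp_edge_plane <- function(vi, vn, w, v_prev = NULL, v_next = NULL) {
  p0 <- if (is.null(v_prev)) vi else v_prev
  p3 <- if (is.null(v_next)) vn else v_next
  .cubic_cr(p0, vi, vn, p3, w)
}

#' Synthesize one plane between two anchors
#'
#' Applies the hybrid rule per pixel: intensity-edge pixels (per `edge_mask`)
#' get cubic convolution along z; interior non-edge pixels get the weighted
#' bilinear average; first/last-column pixels get the 0.75/0.25 boundary
#' variant. Output shape equals input shape.
#'
#' @param interval An [interp_interval()].
#' @param w Fractional position in `[0, 1]`.
#' @param edge_mask Logical matrix from [classify_edge_pixels()] (all-`FALSE`
#'   to force pure weighted bilinear).
#' @param plane_prev,plane_next Optional acquired planes bracketing the
#'   interval, used as outer knots for the cubic z kernel; replicate-clamped
#'   to the anchors when `NULL`.
#' @return Numeric matrix, the synthesized plane.
#' @export
interpolate_plane <- function(interval, w, edge_mask = NULL,
                              plane_prev = NULL, plane_next = NULL) {
  vi <- interval$plane_current
  vn <- interval$plane_next
  nr <- nrow(vi); nc <- ncol(vi)
  if (is.null(edge_mask)) edge_mask <- matrix(FALSE, nr, nc)
  if (!all(dim(edge_mask) == c(nr, nc)))
    mpr_error("edge mask shape must match the planes", "mpr_parameter_error")

  if (nc == 1) {
    out <- (1 - w) * vi + w * vn
  } else {
    # lateral (column) neighbours with replicate clamping at row boundaries
    left  <- cbind(vi[, 1, drop = FALSE], vi[, 1:(nc - 1), drop = FALSE])
    right <- cbind(vi[, 2:nc, drop = FALSE], vi[, nc, drop = FALSE])
    ln    <- cbind(vn[, 1, drop = FALSE], vn[, 1:(nc - 1), drop = FALSE])
    rn    <- cbind(vn[, 2:nc, drop = FALSE], vn[, nc, drop = FALSE])
    out <- (1 - w) * (0.5 * vi + 0.25 * left + 0.25 * right) +
           w * (0.5 * vn + 0.25 * ln + 0.25 * rn)
    # boundary columns: 0.75 self + 0.25 single neighbour
    out[, 1]  <- (1 - w) * (0.75 * vi[, 1] + 0.25 * vi[, 2]) +
                 w * (0.75 * vn[, 1] + 0.25 * vn[, 2])
    out[, nc] <- (1 - w) * (0.75 * vi[, nc] + 0.25 * vi[, nc - 1]) +
                 w * (0.75 * vn[, nc] + 0.25 * vn[, nc - 1])
  }
  if (any(edge_mask)) {
    cub <- .interp_edge_plane(vi, vn, w, plane_prev, plane_next)
    out[edge_mask] <- cub[edge_mask]
  }
  out
}
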