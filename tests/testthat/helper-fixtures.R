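# Fixtures are built in code at test time: tiny slice stacks with explicit
# geometry, plus independent oracles used to cross-check the implementation.

# a minimal axial slice at position z with constant or given pixel values
make_slice <- function(z, value = 100L, nr = 8, nc = 8, instance = NULL,
                       thickness = 2, spacing_tag = thickness,
                       pixel_spacing = 1, matrix_override = NULL,
                       location = z, position = c(0, 0, z)) {
  m <- if (is.null(matrix_override)) matrix(as.integer(value), nr, nc)
       else matrix_override
  slice_record(
    pixel_matrix = m,
    image_position = position,
    orientation = c(1, 0, 0, 0, 1, 0),
    pixel_spacing = c(pixel_spacing, pixel_spacing),
    slice_thickness = thickness,
    spacing_between_slices = spacing_tag,
    instance_number = instance,
    slice_location = location
  )
}

# stack of constant-valued slices, one value per slice, at given z positions
make_stack <- function(z, values = seq_along(z) * 10L, ...) {
  lapply(seq_along(z), function(i)
    make_slice(z[i], value = values[i], instance = i, ...))
}

# independent point-in-polygon oracle: even-odd ray casting, no pracma
ray_cast_inside <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- vx[i] + (py - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# independent bicubic oracle: solve the 16-coefficient linear system from
# value / first-derivative / cross-derivative constraints at the 4 inner
# knots, derivatives by central finite differences (the same completion the
# Catmull-Rom kernel encodes, derived by a different route)
bicubic_oracle <- function(grid, u, v) {
  pow <- function(x, k) ifelse(k < 0, 0, x^pmax(k, 0))
  mono_val <- function(a, b) outer(0:3, 0:3, function(i, j) pow(a, i) * pow(b, j))
  mono_du  <- function(a, b) outer(0:3, 0:3, function(i, j) i * pow(a, i - 1) * pow(b, j))
  mono_dv  <- function(a, b) outer(0:3, 0:3, function(i, j) pow(a, i) * j * pow(b, j - 1))
  mono_duv <- function(a, b) outer(0:3, 0:3, function(i, j) i * j * pow(a, i - 1) * pow(b, j - 1))

  A <- matrix(0, 16, 16); rhs <- numeric(16)
  row <- 0
  for (cu in 0:1) for (cv in 0:1) {
    iu <- 2 + cu; iv <- 2 + cv   # knot indices in the 4x4 grid
    f   <- grid[iu, iv]
    fu  <- (grid[iu + 1, iv] - grid[iu - 1, iv]) / 2
    fv  <- (grid[iu, iv + 1] - grid[iu, iv - 1]) / 2
    fuv <- (grid[iu + 1, iv + 1] - grid[iu + 1, iv - 1] -
            grid[iu - 1, iv + 1] + grid[iu - 1, iv - 1]) / 4
    for (fn in list(list(mono_val, f), list(mono_du, fu),
                    list(mono_dv, fv), list(mono_duv, fuv))) {
      row <- row + 1
      A[row, ] <- as.numeric(fn[[1]](cu, cv))
      rhs[row] <- fn[[2]]
    }
  }
  a <- solve(A, rhs)
  sum(a * as.numeric(outer(0:3, 0:3, function(i, j) u^i * v^j)))
}

# scalar transcription of the weighted-bilinear formulas, independent of the
# vectorized implementation
bilinear_scalar <- function(vi, vn, k, w) {
  (1 - w) * (0.5 * vi[k] + 0.25 * vi[k - 1] + 0.25 * vi[k + 1]) +
    w * (0.5 * vn[k] + 0.25 * vn[k - 1] + 0.25 * vn[k + 1])
}
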