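test_that("length respects anisotropic spacings and metric properties", {
  expect_equal(measure_length(c(3, 3), c(3, 3)), 0)
  expect_equal(measure_length(c(1, 1), c(1, 11), spacing_h = 0.5), 5)
  expect_equal(measure_length(c(0, 0), c(3, 4)), 5)
  set.seed(8)
  for (rep in 1:20) {
    p <- matrix(stats::runif(6, 0, 50), 3, 2)
    sh <- stats::runif(1, 0.2, 2); sv <- stats::runif(1, 0.2, 2)
    d12 <- measure_length(p[1, ], p[2, ], sh, sv)
    d21 <- measure_length(p[2, ], p[1, ], sh, sv)
    expect_equal(d12, d21)
    expect_lte(d12, measure_length(p[1, ], p[3, ], sh, sv) +
                     measure_length(p[3, ], p[2, ], sh, sv) + 1e-12)
  }
})

test_that("angle measures the interior angle at the vertex in mm space", {
  expect_equal(measure_angle(c(0, 1), c(0, 0), c(1, 0)), 90)
  expect_equal(measure_angle(c(0, 5), c(0, 0), c(0, 9)), 0)
  expect_equal(measure_angle(c(0, -2), c(0, 0), c(0, 7)), 180)
  # anisotropy matters: same pixels, different mm angle
  a_iso <- measure_angle(c(1, 1), c(0, 0), c(0, 1))
  a_an <- measure_angle(c(1, 1), c(0, 0), c(0, 1), spacing_h = 1, spacing_v = 3)
  expect_gt(a_an, a_iso)
  expect_error(measure_angle(c(0, 0), c(0, 0), c(1, 1)), class = "mpr_parameter_error")
})

test_that("probe reports rescaled HU at the nearest pixel", {
  m <- matrix(24L, 6, 6); m[3, 4] <- 1024L
  s <- slice_record(m, image_position = c(0, 0, 0),
                    rescale_slope = 1, rescale_intercept = -1024)
  expect_equal(probe(s, c(3, 4)), 0)
  expect_equal(probe(s, c(1, 1)), -1000)
  expect_equal(probe(s, c(2.6, 3.7)), 0)  # nearest-pixel rounding
  expect_error(probe(s, c(0, 3)), class = "mpr_bounds_error")
})

test_that("ROI statistics match hand arithmetic on simple shapes", {
  img <- matrix(10, 20, 20); img[5:14, 5:14] <- 50
  r <- roi_stats(img, roi_shape("rectangle", rbind(c(5, 5), c(14, 14))),
                 spacing_h = 0.5, spacing_v = 0.5)
  expect_equal(r$mean, 50)
  expect_equal(r$sd, 0)
  expect_equal(r$pixel_count, 100)
  expect_equal(r$area_mm2, 25)

  expect_error(roi_stats(img, roi_shape("rectangle", rbind(c(0.1, 0.1), c(0.4, 0.4)))),
               class = "mpr_not_found")
})

test_that("ROI membership equals the brute-force point-in-shape oracle", {
  set.seed(99)
  img <- matrix(stats::runif(32 * 32), 32, 32)
  for (rep in 1:50) {
    kind <- sample(c("rectangle", "ellipse", "freehand"), 1)
    if (kind == "freehand") {
      nv <- sample(3:7, 1)
      # jittered vertices keep pixel centres off the polygon edges
      vr <- stats::runif(nv, 2, 31) + 0.13
      vc <- stats::runif(nv, 2, 31) + 0.21
      # order by angle around the centroid so the polygon is simple
      o <- order(atan2(vr - mean(vr), vc - mean(vc)))
      roi <- roi_shape("freehand", cbind(vr[o], vc[o]))
      oracle <- outer(1:32, 1:32, Vectorize(function(r, cl)
        ray_cast_inside(cl, r, vc[o], vr[o])))
    } else {
      p1 <- stats::runif(2, 1, 16) + 0.3
      p2 <- p1 + stats::runif(2, 2, 14)
      roi <- roi_shape(kind, rbind(p1, p2))
      if (kind == "rectangle") {
        oracle <- outer(1:32, 1:32, function(r, cl)
          r >= p1[1] & r <= p2[1] & cl >= p1[2] & cl <= p2[2])
      } else {
        cr <- (p1[1] + p2[1]) / 2; cc <- (p1[2] + p2[2]) / 2
        ar <- (p2[1] - p1[1]) / 2; ac <- (p2[2] - p1[2]) / 2
        oracle <- outer(1:32, 1:32, function(r, cl)
          ((r - cr) / ar)^2 + ((cl - cc) / ac)^2 <= 1)
      }
    }
    n_oracle <- sum(oracle)
    if (n_oracle == 0) {
      expect_error(roi_stats(img, roi), class = "mpr_not_found")
    } else {
      st <- roi_stats(img, roi)
      expect_equal(st$pixel_count, n_oracle)
      expect_equal(st$mean, mean(img[oracle]))
    }
  }
})

test_that("the error statistic is the mean absolute pairwise difference", {
  expect_equal(error_margin(c(5, 6, 7), c(5, 6, 7))$error, 0)
  expect_equal(error_margin(c(10.0, 10.1), c(10.0, 10.0))$error, 0.05)
  expect_equal(error_margin(9.95, 10.0)$error, 0.05)
  # translation invariance
  m <- c(3.2, 4.4, 9.1); g <- c(3.0, 4.9, 9.0)
  expect_equal(error_margin(m + 17, g + 17)$error, error_margin(m, g)$error)
  expect_error(error_margin(1:3, 1:2), class = "mpr_parameter_error")
})

test_that("half-maximum edges are localized with sub-pixel interpolation", {
  expect_equal(locate_edges_subpixel(c(0, 0, 1000, 1000), 1), 1.5)
  expect_error(locate_edges_subpixel(rep(5, 10)), class = "mpr_not_found")
  e <- locate_edges_subpixel(c(0, 1000, 1000, 0), 1)
  expect_length(e, 2)
  expect_equal(mean(e), 1.5)   # symmetric about the pulse centre
  expect_equal(locate_edges_subpixel(c(0, 0, 1000, 1000), 0.5), 0.75)
})

test_that("extent measurement recovers phantom geometry within half a pixel", {
  spec <- phantom_spec()   # 20 x 20 x 15 mm block, 0.9 mm pixels
  sl <- generate_phantom(spec)
  vol <- build_volume(classify_intervals(order_slices(sl)))
  mid <- round(dim(vol$voxels)[3] / 2)
  ax <- extract_plane(vol, "axial", mid)
  w <- measure_extent(ax, "h", 32)
  expect_lt(abs(w - 20), 0.45 + 1e-9)   # within half a pixel spacing

  # cross-plane consistency: the coronal view reproduces the axial extent
  co <- extract_plane(vol, "coronal", 32)
  expect_lt(abs(measure_extent(co, "h", mid) - w), 0.05)

  expect_error(measure_extent(ax, "h", 1), class = "mpr_not_found")  # background row
})
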