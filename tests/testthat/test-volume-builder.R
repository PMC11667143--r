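test_that("matched depth keeps every plane original; expansion interleaves", {
  sl <- make_stack(c(0, 2, 4, 6, 8), values = rep(50L, 5))
  g <- classify_intervals(order_slices(sl))
  vol <- build_volume(g)
  expect_identical(dim(vol$voxels)[3], 5L)
  expect_true(all(vol$provenance == "original"))

  vol9 <- build_volume(g, target_depth = 9)
  expect_identical(vol9$provenance,
                   rep(c("original", "interpolated"), length.out = 9))
  expect_true(all(vol9$voxels == 50))  # constant conservation, exact
})

test_that("a synthesized mid-plane between flat anchors is their blend", {
  sl <- list(make_slice(0, value = 0L), make_slice(2, value = 8L), make_slice(4, value = 8L))
  g <- classify_intervals(order_slices(sl))
  vol <- build_volume(g, target_depth = 5)
  expect_equal(vol$voxels[, , 2], matrix(4, 8, 8))  # w = 0.5 between 0 and 8
})

test_that("overlap deduplication keeps the lowest instance number per bin", {
  sl <- list(make_slice(0, instance = 1, value = 10L, thickness = 3.75),
             make_slice(1.0, instance = 2, value = 20L, thickness = 3.75),
             make_slice(3.75, instance = 3, value = 30L, thickness = 3.75),
             make_slice(7.5, instance = 4, value = 40L, thickness = 3.75))
  g <- classify_intervals(order_slices(sl))
  g2 <- select_slices_overlap(g)
  expect_equal(g2$z_positions, c(0, 3.75, 7.5))
  expect_identical(vapply(g2$slices, function(s) s$pixel_matrix[1, 1], integer(1)),
                   c(10L, 30L, 40L))
  expect_true(all(diff(g2$z_positions) > 0))

  # identical z, instances {5, 2}: instance 2 survives
  dup <- list(make_slice(0, instance = 5, value = 55L),
              make_slice(0, instance = 2, value = 22L),
              make_slice(2, instance = 7, value = 77L))
  g3 <- select_slices_overlap(classify_intervals(order_slices(dup)))
  expect_identical(vapply(g3$slices, function(s) s$pixel_matrix[1, 1], integer(1)),
                   c(22L, 77L))

  # no overlaps: identity
  g4 <- classify_intervals(order_slices(make_stack(c(0, 2, 4))))
  expect_identical(select_slices_overlap(g4)$z_positions, g4$z_positions)

  # a duplicate slice appears exactly once in the built volume
  vol <- build_volume(classify_intervals(order_slices(dup)))
  expect_identical(dim(vol$voxels)[3], 2L)
})

test_that("gap filling restores approximately nominal sampling", {
  g <- classify_intervals(order_slices(make_stack(c(0, 3.75, 11.25), thickness = 3.75)))
  filled <- fill_gaps(g)
  expect_length(filled$planes, 4)                  # one plane inserted at w = 0.5
  expect_equal(filled$z, c(0, 3.75, 7.5, 11.25))
  expect_identical(filled$provenance,
                   c("original", "original", "interpolated", "original"))

  # all-contiguous series: no insertions
  g2 <- classify_intervals(order_slices(make_stack(c(0, 2, 4))))
  expect_length(fill_gaps(g2)$planes, 3)

  # thin-slice / wide-gap regime: every interval receives insertions and the
  # post-fill sampling is uniform at the slab thickness
  g3 <- classify_intervals(order_slices(
    make_stack(seq(0, 20, by = 5), thickness = 0.625, spacing_tag = 5.0)))
  f3 <- fill_gaps(g3)
  expect_true(all(g3$interval_labels == "gap"))
  expect_equal(diff(f3$z), rep(0.625, 32), tolerance = 1e-12)
})

test_that("original planes are reproduced bit-exactly at their mapped indices", {
  set.seed(5150)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    mats <- lapply(seq_len(n), function(i)
      matrix(sample.int(4000, 36, replace = TRUE), 6, 6))
    sl <- lapply(seq_len(n), function(i)
      make_slice((i - 1) * 2, matrix_override = mats[[i]], instance = i, nr = 6, nc = 6))
    td <- n + sample(0:20, 1)
    vol <- build_volume(classify_intervals(order_slices(sl)), target_depth = td)
    orig_idx <- which(vol$provenance == "original")
    expect_length(orig_idx, n)
    for (i in seq_len(n))
      expect_true(all(vol$voxels[, , orig_idx[i]] == mats[[i]]))
    expect_equal(sum(vol$provenance == "interpolated"), td - n)
  }
})

test_that("volume building is deterministic and conserves constants", {
  sl <- make_stack(c(0, 2, 6, 8, 8, 10), values = rep(200L, 6), thickness = 2)
  g <- classify_intervals(order_slices(sl))
  v1 <- build_volume(g, target_depth = 15)
  v2 <- build_volume(g, target_depth = 15)
  expect_identical(v1$voxels, v2$voxels)
  expect_true(all(v1$voxels == 200))
  expect_identical(dim(v1$voxels)[3], 15L)
})

test_that("plan/geometry mismatch and empty input are rejected", {
  g <- classify_intervals(order_slices(make_stack(c(0, 2, 4))))
  bad_plan <- compute_z_step(7, 14)
  expect_error(build_volume(g, plan = bad_plan), class = "mpr_parameter_error")
})

test_that("volume export writes a parseable sidecar and round-trips planes", {
  dir <- withr::local_tempdir()
  sl <- generate_phantom(phantom_spec(matrix_size = c(16, 16), n_slices = 6, insert_extents = c(8, 8, 10), seed = 3))
  vol <- build_volume(classify_intervals(order_slices(sl)))
  paths <- write_volume_raw(vol, file.path(dir, "vol"))
  side <- jsonlite::read_json(file.path(dir, "vol.json"), simplifyVector = TRUE)
  expect_equal(side$dims, dim(vol$voxels))
  expect_equal(side$spacing_mm[["plane"]], vol$spacing_plane)
  raw <- readBin(file.path(dir, "vol.raw"), "numeric", size = 4,
                 n = prod(dim(vol$voxels)), endian = "little")
  expect_equal(raw[1], vol$voxels[1, 1, 1], tolerance = 1e-6)

  back <- volume_to_slices(vol)
  expect_length(back, dim(vol$voxels)[3])
  expect_identical(back[[1]]$pixel_matrix, sl[[1]]$pixel_matrix)
})
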