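test_that("write/read round-trip is the identity on pixels and metadata", {
  dir <- withr::local_tempdir()
  spec <- phantom_spec(matrix_size = c(16, 16), n_slices = 5, insert_extents = c(8, 8, 10), seed = 7)
  slices <- generate_phantom(spec)
  write_series(slices, dir)
  back <- read_series(dir)

  expect_length(back, 5)
  for (i in seq_along(slices)) {
    a <- slices[[i]]; b <- back[[i]]
    expect_identical(a$pixel_matrix, b$pixel_matrix)
    expect_equal(a$image_position, b$image_position)
    expect_equal(a$orientation, b$orientation)
    expect_equal(a$pixel_spacing_row, b$pixel_spacing_row)
    expect_equal(a$pixel_spacing_col, b$pixel_spacing_col)
    expect_equal(a$slice_thickness, b$slice_thickness)
    expect_equal(a$spacing_between_slices, b$spacing_between_slices)
    expect_identical(a$instance_number, b$instance_number)
    expect_equal(a$slice_location, b$slice_location)
    expect_equal(a$rescale_slope, b$rescale_slope)
    expect_equal(a$rescale_intercept, b$rescale_intercept)
    expect_equal(a$window_center, b$window_center)
    expect_equal(a$window_width, b$window_width)
  }
})

test_that("degenerate spacing tag (thickness 5.0, spacing 0) survives verbatim", {
  # the zero-spacing-tag regime seen in clinical series
  dir <- withr::local_tempdir()
  s <- make_slice(0, thickness = 5.0, spacing_tag = 0, pixel_spacing = 0.8984375)
  write_series(list(s, make_slice(5, thickness = 5.0, spacing_tag = 0,
                                  pixel_spacing = 0.8984375)), dir)
  back <- read_series(dir)
  expect_equal(back[[1]]$slice_thickness, 5.0)
  expect_equal(back[[1]]$spacing_between_slices, 0)
  expect_equal(back[[1]]$pixel_spacing_row, 0.8984375)
})

test_that("absent optional tags round-trip as absent", {
  dir <- withr::local_tempdir()
  s <- slice_record(matrix(1L, 4, 4), image_position = c(0, 0, 0),
                    slice_location = NULL, instance_number = NULL,
                    spacing_between_slices = NULL, slice_thickness = 2)
  write_series(list(s, s), dir)
  back <- read_series(dir)
  expect_null(back[[1]]$slice_location)
  expect_null(back[[1]]$instance_number)
  expect_null(back[[1]]$spacing_between_slices)
})

test_that("invalid input directories raise the dedicated errors", {
  dir <- withr::local_tempdir()
  writeLines("not a dicom", file.path(dir, "readme.txt"))
  expect_error(suppressWarnings(read_series(dir)), class = "mpr_no_input")
  empty <- withr::local_tempdir()
  expect_error(read_series(empty), class = "mpr_no_input")
  expect_error(read_series(file.path(empty, "missing")), class = "mpr_no_input")
  expect_error(write_series(list(), dir), class = "mpr_empty_series")
})

test_that("non-DICOM files are skipped with a warning, valid ones kept", {
  dir <- withr::local_tempdir()
  write_series(make_stack(c(0, 2, 4)), dir)
  writeLines("junk", file.path(dir, "aaa_notes.txt"))
  expect_warning(back <- read_series(dir), "skipping non-DICOM")
  expect_length(back, 3)
})

test_that("mixed matrix dimensions within one series are rejected", {
  dir <- withr::local_tempdir()
  write_series(make_stack(c(0, 2)), file.path(dir, "a"))
  write_series(list(make_slice(4, nr = 4, nc = 4)), file.path(dir, "b"))
  file.copy(list.files(file.path(dir, "a"), full.names = TRUE), dir)
  file.rename(file.path(dir, "b", "slice_0001.dcm"), file.path(dir, "zz.dcm"))
  expect_error(read_series(dir), class = "mpr_inconsistent")
})

test_that("modality rescale is the stated linear map", {
  expect_equal(apply_rescale(1024, 1.0, -1024), 0)
  expect_equal(apply_rescale(57, 1.0, 0), 57)
  expect_equal(apply_rescale(100, 2.0, -50), 150)
  expect_error(apply_rescale(1, 0, 0), class = "mpr_invalid_metadata")
})

test_that("written files parse identically under an independent DICOM reader", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  has_pydicom <- system2("python", c("-c", shQuote("import pydicom")),
                         stdout = FALSE, stderr = FALSE) == 0
  skip_if_not(has_pydicom, "pydicom not importable")

  dir <- withr::local_tempdir()
  s <- make_slice(12.5, value = 321L, nr = 6, nc = 5, instance = 3,
                  thickness = 2.5, spacing_tag = 2.5, pixel_spacing = 0.75)
  path <- write_series(list(s, make_slice(15, nr = 6, nc = 5)), dir)[1]
  out <- system2("python", c("-c", shQuote(paste0(
    "import pydicom; d = pydicom.dcmread('", path, "'); ",
    "print(d.Rows, d.Columns, d.InstanceNumber, d.SliceThickness, ",
    "float(d.ImagePositionPatient[2]), int(d.pixel_array.sum()), ",
    "d.pixel_array[0,0], sep=',')"))), stdout = TRUE)
  vals <- strsplit(out, ",")[[1]]
  expect_equal(as.integer(vals[1]), 6)
  expect_equal(as.integer(vals[2]), 5)
  expect_equal(as.integer(vals[3]), 3)
  expect_equal(as.numeric(vals[4]), 2.5)
  expect_equal(as.numeric(vals[5]), 12.5)
  expect_equal(as.numeric(vals[6]), sum(s$pixel_matrix))
  expect_equal(as.integer(vals[7]), s$pixel_matrix[1, 1])
})
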