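# Single-frame CT DICOM part-10 reader/writer.
#
# Scope is deliberately narrow: uncompressed little-endian transfer syntaxes
# (implicit 1.2.840.10008.1.2 and explicit 1.2.840.10008.1.2.1), one frame per
# file, MONOCHROME2, 16-bit pixels. Compressed syntaxes are rejected with a
# clear error. Stored pixel values are returned untransformed; the modality
# rescale to Hounsfield units is a separate, explicit step (apply_rescale).

.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.SOP_CLASS_CT <- "1.2.840.10008.5.1.4.1.1.2"
.UID_ROOT <- "1.2.826.0.1.3680043.10.1462"

#' Construct a slice record
#'
#' A `slice_record` holds one parsed axial CT slice: the stored-value pixel
#' matrix plus the geometry and display metadata downstream stages need.
#' Stored values are kept as integers; conversion to Hounsfield units is done
#' explicitly via [apply_rescale()].
#'
#' @param pixel_matrix Integer matrix of stored pixel values (rows x cols).
#' @param image_position Numeric length-3, Image Position (Patient), mm, or
#'   `NULL` when absent.
#' @param orientation Numeric length-6 direction cosines: row-axis xyz then
#'   column-axis xyz.
#' @param pixel_spacing Numeric length-2: row spacing then column spacing,
#'   mm/pixel (DICOM Pixel Spacing order: between-rows first).
#' @param slice_thickness Slab thickness, mm, or `NULL`.
#' @param spacing_between_slices Centre-to-centre slice distance, mm, or
#'   `NULL` when the tag is absent.
#' @param instance_number Integer acquisition index, or `NULL`.
#' @param slice_location Relative slice position, mm, or `NULL`.
#' @param rescale_slope,rescale_intercept Modality LUT: HU = stored * slope +
#'   intercept.
#' @param window_center,window_width Default display window.
#' @param source_path Opaque identifier of the originating file.
#' @return An object of class `slice_record`.
#' @export
slice_record <- function(pixel_matrix,
                         image_position = NULL,
                         orientation = c(1, 0, 0, 0, 1, 0),
                         pixel_spacing = c(1, 1),
                         slice_thickness = NULL,
                         spacing_between_slices = NULL,
                         instance_number = NULL,
                         slice_location = NULL,
                         rescale_slope = 1,
                         rescale_intercept = -1024,
                         window_center = 40,
                         window_width = 400,
                         source_path = NA_character_) {
  if (!is.matrix(pixel_matrix) || nrow(pixel_matrix) < 1 || ncol(pixel_matrix) < 1)
    mpr_error("pixel_matrix must be a non-empty matrix", "mpr_invalid_metadata")
  storage.mode(pixel_matrix) <- "integer"
  if (any(pixel_spacing <= 0))
    mpr_error("pixel spacing must be positive", "mpr_invalid_metadata")
  if (length(orientation) != 6)
    mpr_error("orientation must hold 6 direction cosines", "mpr_invalid_metadata")
  r <- orientation[1:3]; c_ <- orientation[4:6]
  if (abs(sqrt(sum(r^2)) - 1) > 1e-4 || abs(sqrt(sum(c_^2)) - 1) > 1e-4)
    mpr_error("orientation triplets must have unit norm", "mpr_invalid_metadata")
  if (abs(sum(r * c_)) > 1e-4)
    mpr_error("orientation triplets must be orthogonal", "mpr_invalid_metadata")
  if (!is.null(image_position) && length(image_position) != 3)
    mpr_error("image_position must be a 3-vector", "mpr_invalid_metadata")
  structure(list(
    pixel_matrix = pixel_matrix,
    rows = nrow(pixel_matrix),
    cols = ncol(pixel_matrix),
    image_position = if (is.null(image_position)) NULL else as.numeric(image_position),
    orientation = as.numeric(orientation),
    pixel_spacing_row = as.numeric(pixel_spacing[1]),
    pixel_spacing_col = as.numeric(pixel_spacing[2]),
    slice_thickness = if (is.null(slice_thickness)) NULL else as.numeric(slice_thickness),
    spacing_between_slices = if (is.null(spacing_between_slices)) NULL else as.numeric(spacing_between_slices),
    instance_number = if (is.null(instance_number)) NULL else as.integer(instance_number),
    slice_location = if (is.null(slice_location)) NULL else as.numeric(slice_location),
    rescale_slope = as.numeric(rescale_slope),
    rescale_intercept = as.numeric(rescale_intercept),
    window_center = as.numeric(window_center),
    window_width = as.numeric(window_width),
    source_path = source_path
  ), class = "slice_record")
}

#' @export
print.slice_record <- function(x, ...) {
  cat(sprintf("<slice_record %dx%d", x$rows, x$cols))
  if (!is.null(x$image_position))
    cat(sprintf(" ipp=(%g,%g,%g)", x$image_position[1], x$image_position[2], x$image_position[3]))
  if (!is.null(x$instance_number)) cat(sprintf(" inst=%d", x$instance_number))
  cat(sprintf(" ps=%gx%g mm>\n", x$pixel_spacing_row, x$pixel_spacing_col))
  invisible(x)
}

#' Modality rescale: stored value to Hounsfield units
#'
#' @param stored_value Stored (raw) pixel value(s).
#' @param slope,intercept Rescale Slope / Intercept from the modality LUT.
#' @return `stored_value * slope + intercept` (HU for CT).
#' @examples
#' apply_rescale(1024, 1, -1024)  # 0 HU (water)
#' @export
apply_rescale <- function(stored_value, slope, intercept) {
  if (length(slope) != 1 || slope == 0)
    mpr_error("rescale slope must be a single non-zero number", "mpr_invalid_metadata")
  stored_value * slope + intercept
}

## ---- binary helpers ---------------------------------------------------------

.u16le <- function(raw, pos) {
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
}
.u32le <- function(raw, pos) {
  # double to stay exact up to 2^32 - 1 (lengths can exceed .Machine$integer.max)
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
    65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])
}
.raw_u16le <- function(x) {
  x <- as.integer(x)
  as.raw(rbind(x %% 256L, (x %/% 256L) %% 256L))
}
.raw_u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

# DICOM DS: decimal string, max 16 bytes per value
.fmt_ds <- function(x) {
  s <- vapply(x, function(v) {
    out <- format(v, scientific = FALSE, trim = TRUE, digits = 12)
    if (nchar(out) > 16) out <- formatC(v, format = "g", digits = 9)
    out
  }, character(1))
  paste(s, collapse = "\\")
}

# one data element, explicit VR little endian
.element <- function(group, elem, vr, value) {
  body <- if (vr %in% c("OW", "OB")) {
    value  # raw already
  } else if (vr == "US") {
    .raw_u16le(value)
  } else { # string VRs arrive pre-formatted
    pad <- if (vr == "UI") as.raw(0L) else charToRaw(" ")
    b <- charToRaw(value)
    if (length(b) %% 2 == 1) b <- c(b, pad)
    b
  }
  header <- c(.raw_u16le(group), .raw_u16le(elem), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(header, as.raw(c(0, 0)), .raw_u32le(length(body)), body)
  } else {
    c(header, .raw_u16le(length(body)), body)
  }
}

.make_uid <- function(...) paste(.UID_ROOT, ..., sep = ".")

## ---- writer -----------------------------------------------------------------

.write_dicom_file <- function(slice, path, series_uid, index) {
  m <- slice$pixel_matrix
  v <- as.integer(t(m))  # row-major per DICOM
  if (any(v < 0L) || any(v > 65535L))
    mpr_error("stored values must fit unsigned 16-bit", "mpr_invalid_metadata")
  pix <- as.raw(rbind(v %% 256L, v %/% 256L))

  sop_uid <- .make_uid(series_uid, index)
  el <- c(
    .element(0x0008, 0x0016, "UI", .SOP_CLASS_CT),
    .element(0x0008, 0x0018, "UI", sop_uid),
    .element(0x0008, 0x0060, "CS", "CT"),
    .element(0x0020, 0x000D, "UI", .make_uid("1", series_uid)),
    .element(0x0020, 0x000E, "UI", .make_uid("2", series_uid))
  )
  if (!is.null(slice$instance_number))
    el <- c(el, .element(0x0020, 0x0013, "IS", as.character(slice$instance_number)))
  if (!is.null(slice$image_position))
    el <- c(el, .element(0x0020, 0x0032, "DS", .fmt_ds(slice$image_position)))
  el <- c(el, .element(0x0020, 0x0037, "DS", .fmt_ds(slice$orientation)))
  if (!is.null(slice$slice_location))
    el <- c(el, .element(0x0020, 0x1041, "DS", .fmt_ds(slice$slice_location)))
  if (!is.null(slice$slice_thickness))
    el <- c(el, .element(0x0018, 0x0050, "DS", .fmt_ds(slice$slice_thickness)))
  if (!is.null(slice$spacing_between_slices))
    el <- c(el, .element(0x0018, 0x0088, "DS", .fmt_ds(slice$spacing_between_slices)))
  el <- c(el,
    .element(0x0028, 0x0002, "US", 1L),
    .element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    .element(0x0028, 0x0010, "US", slice$rows),
    .element(0x0028, 0x0011, "US", slice$cols),
    .element(0x0028, 0x0030, "DS", .fmt_ds(c(slice$pixel_spacing_row, slice$pixel_spacing_col))),
    .element(0x0028, 0x0100, "US", 16L),
    .element(0x0028, 0x0101, "US", 16L),
    .element(0x0028, 0x0102, "US", 15L),
    .element(0x0028, 0x0103, "US", 0L),
    .element(0x0028, 0x1050, "DS", .fmt_ds(slice$window_center)),
    .element(0x0028, 0x1051, "DS", .fmt_ds(slice$window_width)),
    .element(0x0028, 0x1052, "DS", .fmt_ds(slice$rescale_intercept)),
    .element(0x0028, 0x1053, "DS", .fmt_ds(slice$rescale_slope)),
    .element(0x7FE0, 0x0010, "OW", pix)
  )

  # file meta group (always explicit VR LE); (0002,0000) holds the byte length
  # of the meta elements that follow it
  meta_tail <- c(
    .element(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    .element(0x0002, 0x0002, "UI", .SOP_CLASS_CT),
    .element(0x0002, 0x0003, "UI", sop_uid),
    .element(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
    .element(0x0002, 0x0012, "UI", .make_uid("0.1"))
  )
  meta <- c(
    .raw_u16le(0x0002), .raw_u16le(0x0000), charToRaw("UL"), .raw_u16le(4L),
    .raw_u32le(length(meta_tail)),
    meta_tail
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, el), con)
  path
}

#' Write a DICOM series
#'
#' Writes one uncompressed explicit-VR little-endian part-10 file per slice.
#' Re-reading the directory with [read_series()] reproduces every slice
#' field-for-field (pixel data and all metadata carried by `slice_record`).
#'
#' @param slices Non-empty list of [slice_record()] objects with consistent
#'   matrix dimensions.
#' @param directory Output directory (created if missing).
#' @return Character vector of written file paths, one per slice.
#' @export
write_series <- function(slices, directory) {
  if (length(slices) == 0)
    mpr_error("cannot write an empty series", "mpr_empty_series")
  dims <- vapply(slices, function(s) c(s$rows, s$cols), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    mpr_error("inconsistent series: mixed matrix dimensions", "mpr_inconsistent")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) mpr_error(sprintf("cannot create directory '%s'", directory), "mpr_io_error")
  }
  series_uid <- sprintf("%d.%d", length(slices),
                        sum(vapply(slices, function(s) sum(as.numeric(s$pixel_matrix[1, ])), numeric(1))) %% 99991)
  vapply(seq_along(slices), function(i) {
    path <- file.path(directory, sprintf("slice_%04d.dcm", i))
    .write_dicom_file(slices[[i]], path, series_uid, i)
  }, character(1))
}

## ---- reader -----------------------------------------------------------------

# skip an undefined-length sequence/item payload; returns position after the
# matching delimiter. Good enough for the uncommon case of SQ elements in
# scanner metadata we do not interpret.
.skip_undefined <- function(raw, pos) {
  n <- length(raw)
  while (pos + 7 <= n + 1) {
    g <- .u16le(raw, pos); e <- .u16le(raw, pos + 2); len <- .u32le(raw, pos + 4)
    pos <- pos + 8
    if (g == 0xFFFE && e == 0xE0DD) return(pos)        # sequence delimiter
    if (g == 0xFFFE && e == 0xE000) {                  # item
      if (len == 4294967295) pos <- .skip_item_undefined(raw, pos)
      else pos <- pos + len
    } else {
      mpr_error("malformed undefined-length sequence", "mpr_io_error")
    }
  }
  mpr_error("unterminated undefined-length sequence", "mpr_io_error")
}
.skip_item_undefined <- function(raw, pos) {
  n <- length(raw)
  while (pos + 7 <= n + 1) {
    g <- .u16le(raw, pos); e <- .u16le(raw, pos + 2); len <- .u32le(raw, pos + 4)
    if (g == 0xFFFE && e == 0xE00D) return(pos + 8)    # item delimiter
    if (len == 4294967295) { pos <- .skip_undefined(raw, pos + 8) }
    else pos <- pos + 8 + len
  }
  mpr_error("unterminated undefined-length item", "mpr_io_error")
}

.parse_string <- function(raw, pos, len) {
  if (len == 0) return("")
  b <- raw[pos:(pos + len - 1)]
  b <- b[b != as.raw(0)]  # strip UI nul padding
  trimws(rawToChar(b))
}
.parse_ds <- function(raw, pos, len) {
  s <- .parse_string(raw, pos, len)
  if (nchar(s) == 0) return(numeric(0))
  as.numeric(strsplit(s, "\\\\")[[1]])
}

# parse one part-10 file; returns slice_record or NULL when not DICOM
.read_dicom_file <- function(path) {
  sz <- file.size(path)
  if (is.na(sz) || sz < 140) return(NULL)
  raw <- readBin(path, "raw", n = sz)
  if (rawToChar(raw[129:132]) != "DICM") return(NULL)

  tags <- new.env(parent = emptyenv())
  pos <- 133
  n <- length(raw)
  explicit <- TRUE          # meta group is always explicit
  ts <- .TS_EXPLICIT_LE
  in_meta <- TRUE
  meta_end <- Inf

  while (pos + 7 <= n + 1) {
    if (in_meta && pos >= meta_end) {
      in_meta <- FALSE
      if (!(ts %in% c(.TS_IMPLICIT_LE, .TS_EXPLICIT_LE)))
        mpr_error(sprintf("unsupported (compressed?) transfer syntax '%s'", ts), "mpr_unsupported")
      explicit <- identical(ts, .TS_EXPLICIT_LE)
    }
    g <- .u16le(raw, pos); e <- .u16le(raw, pos + 2)
    if (in_meta && g != 0x0002) { # tolerate a missing/short meta group length
      in_meta <- FALSE
      if (!(ts %in% c(.TS_IMPLICIT_LE, .TS_EXPLICIT_LE)))
        mpr_error(sprintf("unsupported (compressed?) transfer syntax '%s'", ts), "mpr_unsupported")
      explicit <- identical(ts, .TS_EXPLICIT_LE)
    }
    use_explicit <- if (in_meta) TRUE else explicit
    if (use_explicit) {
      vr <- rawToChar(raw[(pos + 4):(pos + 5)])
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- .u32le(raw, pos + 8); vstart <- pos + 12
      } else {
        len <- .u16le(raw, pos + 6); vstart <- pos + 8
      }
    } else {
      vr <- NA_character_
      len <- .u32le(raw, pos + 4); vstart <- pos + 8
    }

    if (len == 4294967295) { # undefined length: sequence; skip
      pos <- .skip_undefined(raw, vstart)
      next
    }
    key <- sprintf("%04X%04X", g, e)
    if (in_meta && g == 0x0002) {
      if (e == 0x0000) meta_end <- vstart + len + .u32le(raw, vstart)
      if (e == 0x0010) ts <- .parse_string(raw, vstart, len)
    } else {
      assign(key, list(vstart = vstart, len = len, vr = vr), envir = tags)
    }
    pos <- vstart + len
  }

  gettag <- function(key) if (exists(key, envir = tags)) get(key, envir = tags) else NULL
  num <- function(key) { t <- gettag(key); if (is.null(t) || t$len == 0) NULL else .parse_ds(raw, t$vstart, t$len) }
  us  <- function(key) { t <- gettag(key); if (is.null(t)) NULL else .u16le(raw, t$vstart) }
  istr <- function(key) { t <- gettag(key); if (is.null(t) || t$len == 0) NULL else as.integer(.parse_string(raw, t$vstart, t$len)) }

  rows <- us("00280010"); cols <- us("00280011")
  pd <- gettag("7FE00010")
  if (is.null(rows) || is.null(cols) || is.null(pd)) return(NULL)
  bits <- us("00280100"); if (is.null(bits)) bits <- 16L
  if (bits != 16L)
    mpr_error(sprintf("unsupported bits allocated: %d", bits), "mpr_unsupported")
  nn <- rows * cols
  if (pd$len < 2 * nn)
    mpr_error("pixel data shorter than rows*cols", "mpr_io_error")
  idx <- seq.int(pd$vstart, by = 2L, length.out = nn)
  val <- as.integer(raw[idx]) + 256L * as.integer(raw[idx + 1L])
  pixrep <- us("00280103"); if (is.null(pixrep)) pixrep <- 0L
  if (pixrep == 1L) val <- ifelse(val > 32767L, val - 65536L, val)
  mat <- matrix(val, nrow = rows, ncol = cols, byrow = TRUE)

  ps <- num("00280030"); if (is.null(ps)) ps <- c(1, 1)
  orient <- num("00200037"); if (is.null(orient)) orient <- c(1, 0, 0, 0, 1, 0)
  slope <- num("00281053"); intercept <- num("00281052")
  wc <- num("00281050"); ww <- num("00281051")

  slice_record(
    pixel_matrix = mat,
    image_position = num("00200032"),
    orientation = orient,
    pixel_spacing = ps,
    slice_thickness = num("00180050"),
    spacing_between_slices = num("00180088"),
    instance_number = istr("00200013"),
    slice_location = num("00201041"),
    rescale_slope = if (is.null(slope)) 1 else slope[1],
    rescale_intercept = if (is.null(intercept)) 0 else intercept[1],
    window_center = if (is.null(wc)) 40 else wc[1],
    window_width = if (is.null(ww)) 400 else ww[1],
    source_path = path
  )
}

#' Read a DICOM series from a directory
#'
#' Parses every readable single-frame DICOM file in `directory` (discovery
#' order = lexicographic file name order). Non-DICOM files are skipped with a
#' warning. Stored pixel values are returned untransformed; apply the modality
#' LUT explicitly with [apply_rescale()].
#'
#' @param directory Path containing one series.
#' @return List of [slice_record()] objects, one per valid file.
#' @export
read_series <- function(directory) {
  if (!dir.exists(directory))
    mpr_error(sprintf("no DICOM input: directory '%s' does not exist", directory), "mpr_no_input")
  files <- list.files(directory, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0)
    mpr_error("no DICOM input: directory is empty", "mpr_no_input")
  slices <- list()
  for (f in files) {
    rec <- .read_dicom_file(f)
    if (is.null(rec)) {
      warning(sprintf("skipping non-DICOM file '%s'", basename(f)), call. = FALSE)
      next
    }
    slices[[length(slices) + 1L]] <- rec
  }
  if (length(slices) == 0)
    mpr_error("no DICOM input: no valid DICOM files in directory", "mpr_no_input")
  dims <- vapply(slices, function(s) c(s$rows, s$cols), numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    mpr_error("inconsistent series: mixed matrix dimensions", "mpr_inconsistent")
  slices
}
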