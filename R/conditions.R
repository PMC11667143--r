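# Structured error conditions: every user-facing failure mode carries a stable
# condition class (used by tests) and an exit code (used by the CLI).

.mpr_exit_codes <- c(
  mpr_no_input         = 2L,  # no DICOM input
  mpr_inconsistent     = 3L,  # inconsistent series (mixed dimensions/orientations)
  mpr_empty_series     = 4L,  # zero files after filtering
  mpr_insufficient     = 5L,  # < 2 slices
  mpr_geometry_error   = 6L,  # degenerate orientation etc.
  mpr_bounds_error     = 7L,
  mpr_parameter_error  = 8L,
  mpr_io_error         = 9L,
  mpr_unsupported      = 10L, # compressed / unsupported transfer syntax
  mpr_invalid_metadata = 11L,
  mpr_not_found        = 12L, # structure not found / no edges
  mpr_spec_error       = 13L  # invalid phantom spec
)

mpr_error <- function(message, class) {
  stopifnot(class %in% names(.mpr_exit_codes))
  stop(structure(
    class = c(class, "mpr_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Exit code associated with an error condition
#'
#' Maps a condition raised by this package to the distinct non-zero exit code
#' the command-line front end reports. Unknown errors map to 1.
#'
#' @param cond A condition object.
#' @return Integer exit code.
#' @export
mpr_exit_code <- function(cond) {
  cls <- intersect(class(cond), names(.mpr_exit_codes))
  if (length(cls) == 0) return(1L)
  unname(.mpr_exit_codes[cls[1]])
}
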