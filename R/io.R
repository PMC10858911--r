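#' Read a flash localization table
#'
#' Reads a CSV of 3D flash detections with header
#' `recording_id,frame,x,y,z` (meters, 0-based frames at 30 fps).
#'
#' @param path Path to the CSV file.
#' @return A tibble of flash events.
#' @export
read_localizations <- function(path) {
  if (file.size(path) == 0) {
    return(tibble::tibble(recording_id = character(0), frame = integer(0),
                          x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  ev <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      recording_id = readr::col_character(),
      frame = readr::col_integer(),
      x = readr::col_double(),
      y = readr::col_double(),
      z = readr::col_double()
    ),
    progress = FALSE
  ))
  pr <- readr::problems(ev)
  if (nrow(pr) > 0L) {
    abort(sprintf("malformed localization file %s: line %d, %s",
                  path, pr$row[1] + 1L, pr$expected[1]))
  }
  as_event_table(ev)
}

#' Read a flash sequence table
#'
#' Reads a CSV of binarized flash sequences with header
#' `species,recording_id,start_frame,bits` where `bits` is a 0/1 string
#' (e.g. `110011`). Unknown species codes are allowed; the label encoding
#' simply grows. Write then read is a lossless round trip.
#'
#' @param path Path to the CSV file.
#' @return A labeled sequence table (tibble).
#' @export
read_sequences <- function(path) {
  empty <- tibble::tibble(species = character(0), recording_id = character(0),
                          start_frame = integer(0), bits = character(0))
  if (file.size(path) == 0) return(empty)
  ds <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      species = readr::col_character(),
      recording_id = readr::col_character(),
      start_frame = readr::col_integer(),
      bits = readr::col_character()
    ),
    progress = FALSE
  ))
  if (nrow(ds) == 0L) return(empty)
  pr <- readr::problems(ds)
  if (nrow(pr) > 0L) {
    abort(sprintf("malformed sequence file %s: line %d, %s",
                  path, pr$row[1] + 1L, pr$expected[1]))
  }
  bad <- which(is.na(ds$bits) | !grepl("^[01]+$", ds$bits))
  if (length(bad) > 0L) {
    abort(sprintf("malformed sequence file %s: line %d, bits must be a 0/1 string",
                  path, bad[1] + 1L))
  }
  tibble::as_tibble(ds)
}

#' Write a flash sequence table
#'
#' @param ds A sequence table. Missing `species`, `recording_id` or
#'   `start_frame` columns are written as `NA`.
#' @param path Output CSV path.
#' @return `ds`, invisibly.
#' @export
write_sequences <- function(ds, path) {
  ds <- as_sequence_table(ds)
  if (!"species" %in% names(ds)) ds$species <- NA_character_
  if (!"recording_id" %in% names(ds)) ds$recording_id <- NA_character_
  if (!"start_frame" %in% names(ds)) ds$start_frame <- NA_integer_
  readr::write_csv(
    ds[, c("species", "recording_id", "start_frame", "bits")],
    path, progress = FALSE
  )
  invisible(ds)
}

#' Read a flash pattern specification
#'
#' Reads a CSV of alternating on/off segment durations with header
#' `species,state,duration_s`, in pattern order. See
#' [literature_patterns()] for the bundled published patterns.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `species`, `state` (`"on"`/`"off"`) and
#'   `duration_s`.
#' @export
read_pattern_specs <- function(path) {
  ps <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(
      species = readr::col_character(),
      state = readr::col_character(),
      duration_s = readr::col_double()
    ),
    progress = FALSE
  ))
  pr <- readr::problems(ps)
  if (nrow(pr) > 0L) {
    abort(sprintf("malformed pattern file %s: line %d, %s",
                  path, pr$row[1] + 1L, pr$expected[1]))
  }
  if (!all(ps$state %in% c("on", "off"))) {
    abort("pattern `state` must be \"on\" or \"off\".")
  }
  tibble::as_tibble(ps)
}
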