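# Literature flash-pattern parameters (flash count, inter-flash gap s,
# flash duration s) for the six species with a published reference pattern.
# B. wickershamorum has no published reference and is deliberately absent.
lit_params <- function() {
  tibble::tribble(
    ~species,            ~n_flashes, ~gap_s, ~duration_s,
    "P. bethaniensis",   2L,         0.53,   0.27,
    "P. carolinus",      9L,         0.37,   0.23,
    "P. forresti",       5L,         0.10,   0.16,
    "P. frontalis",      10L,        0.87,   0.13,
    "P. knulli",         3L,         0.32,   0.20,
    "P. obscurellus",    3L,         0.28,   0.22
  )
}

#' Published literature flash patterns
#'
#' Returns the published characteristic flash patterns of the six species
#' for which one exists, as alternating on/off segment durations (seconds).
#' Each pattern is `n` flashes of the published flash duration separated by
#' the published inter-flash gap. *B. wickershamorum* has no published
#' reference pattern and is represented by its absence, never by a zero
#' template. The same table ships as a CSV fixture in
#' `system.file("extdata", "literature_patterns.csv", package = "fireflash")`.
#'
#' @return A tibble with columns `species`, `state` (`"on"`/`"off"`) and
#'   `duration_s`, in pattern order per species.
#' @export
literature_patterns <- function() {
  lp <- lit_params()
  purrr::pmap_dfr(lp, function(species, n_flashes, gap_s, duration_s) {
    k <- 2L * n_flashes - 1L
    tibble::tibble(
      species = species,
      state = rep(c("on", "off"), length.out = k),
      duration_s = rep(c(duration_s, gap_s), length.out = k)
    )
  })
}

#' Encode a flash pattern specification as a binary reference
#'
#' Converts alternating on/off segment durations into a binary time series
#' at `fps` samples per second: each segment becomes
#' `round(duration_s * fps)` bits of its state, with a floor of 1 bit.
#'
#' @param spec A pattern specification for one species: a data frame with
#'   columns `state` (`"on"`/`"off"`) and `duration_s` (> 0), starting and
#'   ending with an `"on"` segment.
#' @param fps Frames per second. Default 30.
#' @return A numeric 0/1 vector.
#' @export
encode_literature_reference <- function(spec, fps = 30) {
  if (!is.data.frame(spec) || !all(c("state", "duration_s") %in% names(spec))) {
    abort("`spec` must be a data frame with `state` and `duration_s` columns.")
  }
  if (nrow(spec) == 0L) abort("`spec` must have at least one segment.")
  if (any(spec$duration_s <= 0)) abort("segment durations must be > 0.")
  if (!all(spec$state %in% c("on", "off"))) {
    abort("`state` must be \"on\" or \"off\".")
  }
  if (spec$state[1] != "on" || spec$state[nrow(spec)] != "on") {
    abort("a pattern must start and end with an \"on\" segment.")
  }
  n_bits <- pmax(1L, as.integer(round_half_away(spec$duration_s * fps)))
  rep(as.numeric(spec$state == "on"), times = n_bits)
}

#' Encode all literature references
#'
#' @param fps Frames per second. Default 30.
#' @return A tibble with one row per species with a published pattern:
#'   `species`, `values` (list-column of 0/1 vectors), `provenance`.
#' @export
literature_references <- function(fps = 30) {
  pats <- literature_patterns()
  pats |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      values = list(encode_literature_reference(
        dplyr::pick(dplyr::everything()), fps = fps)),
      .groups = "drop"
    ) |>
    dplyr::mutate(provenance = "literature")
}

#' Build a population reference from training sequences
#'
#' A population reference is the elementwise average of a species' training
#' sequences: since every sequence starts with a flash, sequences are
#' left-aligned at their first bit, zero-padded on the right to the longest
#' length, and averaged, giving a real-valued template in \[0, 1\].
#'
#' @param train A sequence table of one species (all `species` values equal,
#'   if the column is present), or a character vector of 0/1 strings.
#' @return A numeric vector in \[0, 1\] whose length is the maximum training
#'   sequence length.
#' @export
build_population_reference <- function(train) {
  if (is.character(train)) train <- tibble::tibble(bits = train)
  train <- as_sequence_table(train)
  if (nrow(train) == 0L) abort("`train` must contain at least one sequence.")
  if ("species" %in% names(train) && length(unique(train$species)) > 1L) {
    abort("`train` must contain sequences of a single species.")
  }
  vs <- bits_to_vecs(train$bits)
  len <- max(lengths(vs))
  acc <- numeric(len)
  for (v in vs) acc[seq_along(v)] <- acc[seq_along(v)] + v
  acc / length(vs)
}

#' Build population references for every species in a training set
#'
#' @param train A labeled sequence table.
#' @return A tibble with columns `species`, `values` (list-column of
#'   real-valued templates) and `provenance`.
#' @export
population_references <- function(train) {
  train <- as_sequence_table(train, labeled = TRUE)
  train |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(values = list(build_population_reference(.data$bits)),
                     .groups = "drop") |>
    dplyr::mutate(provenance = "population")
}
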