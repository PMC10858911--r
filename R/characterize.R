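#' Select the most confidently correct classifications
#'
#' The confidence filter used for data-driven characterization: for each
#' sequence take the maximum softmax probability; keep the pair
#' (probability, index) only when the arg max equals the true label; sort by
#' probability, descending (ties broken by ascending dataset index), and
#' return the sequences at the top `n` indices -- all of them if fewer than
#' `n` qualify.
#'
#' @param ds A labeled sequence table (the test set).
#' @param preds A prediction tibble aligned row-for-row with `ds` (from any
#'   of the package's classifiers).
#' @param n Subset size. Default 100.
#' @return The selected rows of `ds` with an added `confidence` column, in
#'   descending confidence order. Empty (with a warning) if nothing was
#'   classified correctly.
#' @export
top_confident_subset <- function(ds, preds, n = 100) {
  ds <- as_sequence_table(ds, labeled = TRUE)
  if (!is.data.frame(preds) ||
      !all(c("predicted", "confidence") %in% names(preds)) ||
      nrow(preds) != nrow(ds)) {
    abort("`preds` must be a prediction tibble aligned with `ds`.")
  }
  ok <- which(preds$predicted == ds$species)
  if (length(ok) == 0L) {
    warn("no correct predictions; returning an empty subset.")
    out <- ds[integer(0), , drop = FALSE]
    out$confidence <- numeric(0)
    return(out)
  }
  ord <- ok[order(-preds$confidence[ok], ok)]
  keep <- head(ord, n)
  out <- ds[keep, , drop = FALSE]
  out$confidence <- preds$confidence[keep]
  out
}

#' Characterize a population's flash patterns
#'
#' Pools trajectory-level statistics across the sequences of one population:
#' one flash count per sequence, and every flash duration and inter-flash
#' gap contributing once (event-level pooling). Emits normalized histograms
#' (masses summing to 1) and mean +/- sd per statistic.
#'
#' @param ds A cleaned sequence table of one population.
#' @param fps Frames per second. Default 30.
#' @param count_bin Histogram bin width for flash counts. Default 1.
#' @param time_bin Histogram bin width (s) for durations and gaps. Default
#'   one frame, 1/30 s.
#' @param population Optional population identifier stored in the result.
#' @return An object of class `firefly_characterization` with elements
#'   `population`, `n_sequences`, `summary` (statistic, mean, sd, n) and
#'   `histograms` (statistic, bin_left, bin_right, mass).
#' @export
characterize_population <- function(ds, fps = 30, count_bin = 1,
                                    time_bin = 1 / 30, population = NULL) {
  ds <- as_sequence_table(ds)
  if (nrow(ds) == 0L) abort("`ds` must contain at least one sequence.")
  st <- sequence_stats(ds, fps = fps)
  counts <- st$n_flashes
  durs <- unlist(st$flash_durations_s, use.names = FALSE)
  gaps <- unlist(st$gaps_s, use.names = FALSE)
  stat_tbl <- function(name, values) {
    tibble::tibble(statistic = name,
                   mean = if (length(values)) mean(values) else NA_real_,
                   sd = if (length(values) > 1) sd(values) else
                     if (length(values) == 1) 0 else NA_real_,
                   n = length(values))
  }
  summary <- dplyr::bind_rows(
    stat_tbl("n_flashes", counts),
    stat_tbl("gap_s", gaps),
    stat_tbl("duration_s", durs)
  )
  histograms <- dplyr::bind_rows(
    hist_mass("n_flashes", counts, count_bin, origin = -count_bin / 2),
    hist_mass("gap_s", gaps, time_bin),
    hist_mass("duration_s", durs, time_bin)
  )
  structure(
    list(population = population %||% NA_character_,
         n_sequences = nrow(ds), summary = summary, histograms = histograms),
    class = "firefly_characterization"
  )
}

# Normalized histogram over fixed-width bins anchored at `origin`.
hist_mass <- function(name, values, width, origin = 0) {
  if (length(values) == 0L) {
    return(tibble::tibble(statistic = character(0), bin_left = numeric(0),
                          bin_right = numeric(0), mass = numeric(0)))
  }
  bin <- floor((values - origin) / width + 1e-9)
  tab <- table(bin)
  b <- as.numeric(names(tab))
  tibble::tibble(
    statistic = name,
    bin_left = origin + b * width,
    bin_right = origin + (b + 1) * width,
    mass = as.numeric(tab) / length(values)
  )
}

#' @export
print.firefly_characterization <- function(x, ...) {
  cat(sprintf("<firefly_characterization> %s (%d sequences)\n",
              x$population, x$n_sequences))
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.firefly_characterization <- function(x, ...) {
  x$histograms
}

#' @exportS3Method generics::glance
glance.firefly_characterization <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    population = x$population,
    n_sequences = x$n_sequences,
    n_flashes_mean = s$mean[s$statistic == "n_flashes"],
    n_flashes_sd = s$sd[s$statistic == "n_flashes"],
    gap_s_mean = s$mean[s$statistic == "gap_s"],
    gap_s_sd = s$sd[s$statistic == "gap_s"],
    duration_s_mean = s$mean[s$statistic == "duration_s"],
    duration_s_sd = s$sd[s$statistic == "duration_s"]
  )
}

#' Published literature values of the three flash statistics
#'
#' @return A tibble with one row per species: `species`, `n_flashes`,
#'   `gap_s`, `duration_s`. *B. wickershamorum* has no published values and
#'   appears with `NA`s.
#' @export
literature_values <- function() {
  dplyr::bind_rows(
    tibble::tibble(species = "B. wickershamorum", n_flashes = NA_integer_,
                   gap_s = NA_real_, duration_s = NA_real_),
    lit_params()
  ) |> dplyr::arrange(.data$species)
}

#' Compare a characterization to the literature values
#'
#' @param char A `firefly_characterization`.
#' @param species Species name to look up in [literature_values()].
#' @return A tibble with `statistic`, `data_mean`, `literature`, `delta`
#'   (data minus literature; `NA` where no literature value exists).
#' @export
compare_to_literature <- function(char, species) {
  stopifnot(inherits(char, "firefly_characterization"))
  lv <- literature_values()
  row <- lv[lv$species == species, , drop = FALSE]
  if (nrow(row) == 0L) {
    row <- tibble::tibble(species = species, n_flashes = NA_integer_,
                          gap_s = NA_real_, duration_s = NA_real_)
  }
  lit <- c(n_flashes = as.numeric(row$n_flashes), gap_s = row$gap_s,
           duration_s = row$duration_s)
  s <- char$summary
  tibble::tibble(
    statistic = s$statistic,
    data_mean = s$mean,
    literature = unname(lit[s$statistic]),
    delta = .data$data_mean - .data$literature
  )
}

#' Write a characterization to CSV files
#'
#' Writes the normalized histograms (`statistic,bin_left,bin_right,mass`)
#' and a one-row summary mirroring the mean +/- sd layout.
#'
#' @param char A `firefly_characterization`.
#' @param hist_path,summary_path Output CSV paths.
#' @return `char`, invisibly.
#' @export
write_characterization <- function(char, hist_path, summary_path) {
  stopifnot(inherits(char, "firefly_characterization"))
  readr::write_csv(char$histograms, hist_path, progress = FALSE)
  readr::write_csv(glance(char), summary_path, progress = FALSE)
  invisible(char)
}
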