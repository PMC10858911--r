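#' Held-out recording days for the sympatry experiments
#'
#' One recording day is held out from training for each of five species
#' (the two remaining species have only two recordings each and are never
#' held out, though they stay in the training set and can still be
#' predicted).
#'
#' @return A tibble with columns `day`, `species`, `code`.
#' @export
holdout_table <- function() {
  tibble::tribble(
    ~day,               ~species,            ~code,
    "May 20, 2020",     "P. frontalis",      "s0524uf",
    "June 13, 2020",    "P. carolinus",      "s0613ic",
    "June 2, 2021",     "P. obscurellus",    "s1602io",
    "August 9, 2021",   "P. knulli",         "s1809ik",
    "June 24, 2022",    "B. wickershamorum", "s2624bw"
  )
}

#' Composition of a mixed-species test set
#'
#' @param proportion Minority-species proportion, in (0, 0.5].
#' @param total Total number of sequences in the mixture. Default 400.
#' @return A named integer vector `c(minority = ..., majority = ...)`;
#'   e.g. proportion 0.005 gives 2 minority and 398 majority sequences, and
#'   proportion 0.5 gives 200 of each.
#' @export
sympatry_mix_counts <- function(proportion, total = 400) {
  if (proportion <= 0 || proportion > 0.5) {
    abort("`proportion` must be in (0, 0.5].")
  }
  n_min <- as.integer(round_half_away(proportion * total))
  if (n_min < 1L) {
    abort(sprintf("proportion %g of %d sequences yields no minority sequence.",
                  proportion, total))
  }
  c(minority = n_min, majority = as.integer(total) - n_min)
}

#' Artificial-sympatry experiment
#'
#' Tests whether a classifier trained on species recorded in isolation can
#' detect both species of a hypothetical sympatric swarm. For every ordered
#' pair of held-out species and every mixing proportion `p`, a test set of
#' `total` sequences is sampled from the held-out data --
#' `round(p * total)` of the minority species and the rest of the majority
#' species, with replacement when a held-out day is smaller than requested
#' -- and each species' true-positive rate (its identification rate) is
#' recorded and averaged over `n_iter` iterations.
#'
#' Because inference is deterministic, each held-out sequence is classified
#' once up front and iterations only resample indices; the Monte Carlo
#' estimate is identical to reclassifying every sample.
#'
#' @param model A trained classifier with a [predict()] method returning a
#'   `predicted` column (`fireflash_gru` or `fireflash_svm`), or `NULL` if
#'   `holdout` already contains a `predicted` column.
#' @param holdout A labeled sequence table of held-out sequences (>= 2
#'   species). With `model = NULL` it must also carry `predicted`.
#' @param proportions Minority proportions in (0, 0.5]. Default spans 0.005
#'   (2 of 400) to 0.5 (200 of 400).
#' @param n_iter Iterations per pair and proportion. Default 500.
#' @param total Mixture size. Default 400.
#' @param seed Integer seed for the resampling.
#' @return A tibble of class `fireflash_sympatry`: one row per ordered pair,
#'   proportion and species, with `majority`, `minority`, `proportion`,
#'   `species`, `role`, `identification_rate`, `n_iter`.
#' @export
sympatry_experiment <- function(model, holdout,
                                proportions = c(0.005, 0.01, 0.02, 0.05,
                                                0.1, 0.2, 0.3, 0.4, 0.5),
                                n_iter = 500, total = 400, seed = 1L) {
  holdout <- as_sequence_table(holdout, labeled = TRUE)
  if (is.null(model)) {
    if (!"predicted" %in% names(holdout)) {
      abort("with `model = NULL`, `holdout` must have a `predicted` column.")
    }
    predicted <- holdout$predicted
  } else {
    predicted <- predict(model, holdout)$predicted
  }
  species <- sort(unique(holdout$species))
  if (length(species) < 2L) abort("`holdout` must contain >= 2 species.")
  correct <- predicted == holdout$species
  by_sp <- split(seq_len(nrow(holdout)), holdout$species)
  pairs <- expand.grid(majority = species, minority = species,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$majority != pairs$minority, , drop = FALSE]
  res <- withr::with_seed(seed, {
    purrr::pmap_dfr(pairs, function(majority, minority) {
      maj_pool <- by_sp[[majority]]
      min_pool <- by_sp[[minority]]
      purrr::map_dfr(proportions, function(p) {
        nn <- sympatry_mix_counts(p, total)
        tpr_min <- numeric(n_iter)
        tpr_maj <- numeric(n_iter)
        for (it in seq_len(n_iter)) {
          smin <- sample(min_pool, nn[["minority"]],
                         replace = length(min_pool) < nn[["minority"]])
          smaj <- sample(maj_pool, nn[["majority"]],
                         replace = length(maj_pool) < nn[["majority"]])
          tpr_min[it] <- mean(correct[smin])
          tpr_maj[it] <- mean(correct[smaj])
        }
        tibble::tibble(
          majority = majority, minority = minority, proportion = p,
          species = c(minority, majority),
          role = c("minority", "majority"),
          identification_rate = c(mean(tpr_min), mean(tpr_maj)),
          n_iter = n_iter
        )
      })
    })
  })
  class(res) <- c("fireflash_sympatry", class(res))
  res
}
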