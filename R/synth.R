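#' Generative distribution parameters for one firefly population
#'
#' Flash patterns are emulated as alternating flash/gap pulse trains whose
#' flash count, flash duration and inter-flash gap are independent normal
#' draws quantized to the frame grid. Means and standard deviations are
#' typically taken from field characterizations (see [preset_table2()]).
#'
#' @param name Population or species label.
#' @param count_mean,count_sd Flashes per trajectory (mean >= 2, sd >= 0).
#' @param gap_mean_s,gap_sd_s Inter-flash gap, seconds.
#' @param dur_mean_s,dur_sd_s Flash duration, seconds.
#' @param fps Frames per second. Default 30.
#' @return A one-row tibble of class `species_params`.
#' @export
species_params <- function(name, count_mean, count_sd,
                           gap_mean_s, gap_sd_s, dur_mean_s, dur_sd_s,
                           fps = 30) {
  if (count_mean < 2) abort("`count_mean` must be >= 2.")
  if (gap_mean_s <= 0 || dur_mean_s <= 0) abort("means must be positive.")
  if (count_sd < 0 || gap_sd_s < 0 || dur_sd_s < 0) abort("sds must be >= 0.")
  out <- tibble::tibble(
    name = name, count_mean = count_mean, count_sd = count_sd,
    gap_mean_s = gap_mean_s, gap_sd_s = gap_sd_s,
    dur_mean_s = dur_mean_s, dur_sd_s = dur_sd_s, fps = fps
  )
  class(out) <- c("species_params", class(out))
  out
}

as_species_params <- function(params) {
  need <- c("name", "count_mean", "count_sd", "gap_mean_s", "gap_sd_s",
            "dur_mean_s", "dur_sd_s")
  if (!is.data.frame(params) || !all(need %in% names(params)) ||
      nrow(params) != 1L) {
    abort("`params` must be a one-row species_params table; see species_params() or preset_table2().")
  }
  if (!"fps" %in% names(params)) params$fps <- 30
  species_params(params$name, params$count_mean, params$count_sd,
                 params$gap_mean_s, params$gap_sd_s,
                 params$dur_mean_s, params$dur_sd_s, params$fps)
}

#' Field-characterized population presets
#'
#' The twelve filmed populations with the mean and standard deviation of
#' their flash count, inter-flash gap and flash duration, as generative
#' parameters for the synthetic sequence generator.
#'
#' @return A tibble with one row per population: `name` (species, site,
#'   date), `species`, and the six distribution parameters plus `fps`.
#' @export
preset_table2 <- function() {
  t2 <- tibble::tribble(
    ~species,            ~site, ~date,        ~count_mean, ~count_sd, ~gap_mean_s, ~gap_sd_s, ~dur_mean_s, ~dur_sd_s,
    "B. wickershamorum", "AZ",  "Jul. 2022",  5.9,         2.5,       0.82,        0.07,      0.17,        0.03,
    "P. bethaniensis",   "DE",  "Jul. 2022",  2.3,         0.6,       0.22,        0.04,      0.07,        0.03,
    "P. carolinus",      "TN",  "Jun. 2020",  7.2,         1.9,       0.42,        0.04,      0.14,        0.03,
    "P. carolinus",      "OH",  "Jun. 2022",  5.7,         1.1,       0.42,        0.04,      0.10,        0.02,
    "P. carolinus",      "PA",  "Jun. 2022",  5.9,         1.4,       0.43,        0.03,      0.11,        0.03,
    "P. forresti",       "GA",  "Jun. 2022",  4.7,         2.3,       0.51,        0.20,      0.08,        0.04,
    "P. frontalis",      "SC",  "May 2020",   15.7,        4.3,       0.63,        0.07,      0.04,        0.003,
    "P. frontalis",      "TN",  "Jun. 2021",  12.2,        4.1,       0.69,        0.09,      0.04,        0.005,
    "P. knulli",         "AZ",  "Aug. 2021",  2.7,         0.4,       0.34,        0.01,      0.10,        0.03,
    "P. knulli",         "AZ",  "Aug. 2022",  2.4,         0.6,       0.33,        0.02,      0.06,        0.02,
    "P. obscurellus",    "MA",  "Jun. 2021",  2.4,         0.6,       0.39,        0.05,      0.21,        0.05,
    "P. obscurellus",    "MA",  "Jun. 2022",  2.2,         0.4,       0.42,        0.07,      0.23,        0.12
  )
  t2$name <- paste(t2$species, t2$site, t2$date, sep = ", ")
  t2$fps <- 30
  t2[, c("name", "species", "site", "date", "count_mean", "count_sd",
         "gap_mean_s", "gap_sd_s", "dur_mean_s", "dur_sd_s", "fps")]
}

# Draw one pulse train under the current RNG state.
# Flash count: round of a normal draw, floored at `count_floor`.
# Durations: independent normal draws quantized to >= `dur_floor` frames.
# Gaps: independent normal draws quantized to >= `gap_floor` frames (3 by
# default so generated data is a fixed point of clean_short_gaps()).
# Quantization rounds half away from zero for cross-platform determinism.
draw_sequence <- function(p, count_floor, gap_floor, dur_floor) {
  k <- max(count_floor, round_half_away(rnorm(1, p$count_mean, p$count_sd)))
  dur <- pmax(dur_floor,
              round_half_away(rnorm(k, p$dur_mean_s, p$dur_sd_s) * p$fps))
  gap <- if (k > 1) {
    pmax(gap_floor,
         round_half_away(rnorm(k - 1, p$gap_mean_s, p$gap_sd_s) * p$fps))
  } else integer(0)
  n_runs <- 2L * k - 1L
  lens <- integer(n_runs)
  lens[seq(1L, n_runs, by = 2L)] <- dur
  if (k > 1) lens[seq(2L, n_runs, by = 2L)] <- gap
  vals <- rep_len(c(1L, 0L), n_runs)
  paste(strrep(c("1", "0")[2L - vals], lens), collapse = "")
}

#' Sample one synthetic flash sequence
#'
#' @param params A `species_params` row.
#' @param seed Optional integer seed.
#' @param count_floor Minimum flash count (default 2, mirroring the
#'   single-flash threshold so no generated sequence is discarded).
#' @param gap_floor Minimum gap in frames (default 3, so the short-gap
#'   cleaning rule is a no-op on generated data).
#' @param dur_floor Minimum flash duration in frames. Default 1.
#' @return A 0/1 string starting and ending with a flash.
#' @export
sample_sequence <- function(params, seed = NULL, count_floor = 2L,
                            gap_floor = 3L, dur_floor = 1L) {
  p <- as_species_params(params)
  draw <- function() draw_sequence(p, count_floor, gap_floor, dur_floor)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic population of flash sequences
#'
#' `n` independent pulse trains drawn from the population's parameters and
#' labeled with its name; the same seed reproduces the dataset bit-exactly.
#'
#' @inheritParams sample_sequence
#' @param n Number of sequences.
#' @param seed Integer seed.
#' @param recording_id Recording label for the output table.
#' @return A labeled sequence table.
#' @export
generate_population <- function(params, n, seed = 1L, recording_id = "synth",
                                count_floor = 2L, gap_floor = 3L,
                                dur_floor = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  p <- as_species_params(params)
  bits <- withr::with_seed(seed, {
    vapply(seq_len(n),
           function(i) draw_sequence(p, count_floor, gap_floor, dur_floor),
           character(1))
  })
  tibble::tibble(species = p$name, recording_id = recording_id,
                 start_frame = 0L, bits = bits)
}

#' Swarm simulation configuration
#'
#' @param arena_m Arena extents (m), a length-3 positive vector.
#' @param speed_m_per_frame Random-walk step scale per frame (m).
#' @param noise_sd_m Detection noise sd added to each coordinate (m).
#' @param drop_prob Probability that an on-frame detection is dropped.
#' @param max_start_frame Fireflies begin their pattern at a uniform frame
#'   in `[0, max_start_frame]`.
#' @return A `swarm_config` list.
#' @export
swarm_config <- function(arena_m = c(10, 10, 5), speed_m_per_frame = 0.01,
                         noise_sd_m = 0, drop_prob = 0,
                         max_start_frame = 120L) {
  stopifnot(length(arena_m) == 3, all(arena_m > 0), speed_m_per_frame >= 0,
            noise_sd_m >= 0, drop_prob >= 0, drop_prob <= 1,
            max_start_frame >= 0)
  structure(list(arena_m = arena_m, speed_m_per_frame = speed_m_per_frame,
                 noise_sd_m = noise_sd_m, drop_prob = drop_prob,
                 max_start_frame = as.integer(max_start_frame)),
            class = "swarm_config")
}

#' Simulate a spatially embedded firefly swarm
#'
#' Each simulated firefly performs a Gaussian random walk through the arena
#' and emits the on-frames of its sampled flash sequence as 3D flash
#' detections (with optional positional noise and frame drops). The planted
#' truth (`firefly` id and `species` per event) is returned alongside the
#' detection columns, so trajectorization can be validated against it.
#'
#' @param params A params table: one row per population
#'   (see [species_params()] / [preset_table2()]).
#' @param n_fireflies Integer vector, fireflies per population row.
#' @param cfg A [swarm_config()].
#' @param seed Integer seed.
#' @param recording_id Recording label.
#' @param positions Optional matrix of starting positions (one row per
#'   firefly, columns x,y,z); default uniform in the arena.
#' @return A tibble of events: `recording_id`, `frame`, `x`, `y`, `z`, plus
#'   planted-truth columns `firefly` and `species`.
#' @export
generate_swarm_events <- function(params, n_fireflies, cfg = swarm_config(),
                                  seed = 1L, recording_id = "synth",
                                  positions = NULL) {
  stopifnot(inherits(cfg, "swarm_config"))
  if (!is.data.frame(params)) abort("`params` must be a params table.")
  if (length(n_fireflies) == 1L) {
    n_fireflies <- rep(as.integer(n_fireflies), nrow(params))
  }
  stopifnot(length(n_fireflies) == nrow(params))
  total <- sum(n_fireflies)
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    stopifnot(nrow(positions) == total, ncol(positions) == 3)
  }
  withr::with_seed(seed, {
    out <- vector("list", total)
    ff <- 0L
    for (pi in seq_len(nrow(params))) {
      p <- as_species_params(params[pi, , drop = FALSE])
      for (j in seq_len(n_fireflies[pi])) {
        ff <- ff + 1L
        v <- bits_to_vec(draw_sequence(p, 2L, 3L, 1L))
        start <- if (cfg$max_start_frame > 0) {
          sample.int(cfg$max_start_frame + 1L, 1L) - 1L
        } else 0L
        frames <- start + which(v == 1L) - 1L
        span <- max(frames) - start + 1L
        pos0 <- if (is.null(positions)) {
          runif(3) * cfg$arena_m
        } else positions[ff, ]
        steps <- matrix(rnorm(3L * span, sd = cfg$speed_m_per_frame),
                        span, 3L)
        path <- if (span == 1L) {
          matrix(pos0 + steps, 1L, 3L)
        } else {
          sweep(apply(steps, 2L, cumsum), 2L, pos0, "+")
        }
        rel <- frames - start + 1L
        keep <- runif(length(frames)) >= cfg$drop_prob
        if (!any(keep)) next
        xyz <- path[rel[keep], , drop = FALSE] +
          matrix(rnorm(3L * sum(keep), sd = cfg$noise_sd_m), sum(keep), 3L)
        out[[ff]] <- tibble::tibble(
          recording_id = recording_id, frame = frames[keep],
          x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
          firefly = ff, species = p$name
        )
      }
    }
    dplyr::bind_rows(out) |> dplyr::arrange(.data$frame)
  })
}
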