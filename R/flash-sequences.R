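#' Convert a frame count to seconds
#'
#' Recordings are made at 30 frames per second, so 30 bits of a binarized
#' flash sequence represent one full second.
#'
#' @param n_frames Number of frames (non-negative).
#' @param fps Frames per second (positive). Default 30.
#' @return Duration in seconds, `n_frames / fps`.
#' @examples
#' frames_to_seconds(30)        # 1 s
#' frames_to_seconds(6)         # 0.2 s
#' @export
frames_to_seconds <- function(n_frames, fps = 30) {
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    abort("`fps` must be a single positive number.")
  }
  if (any(n_frames < 0)) abort("`n_frames` must be non-negative.")
  n_frames / fps
}

#' Link flash detections into streaks
#'
#' A streak is a run of flash detections at strictly consecutive frames in
#' which each consecutive pair of detections lies within a small spatial
#' radius; it corresponds to one continuous flash as the insect moves.
#' When several detections share a frame, active streaks are extended
#' greedily by ascending distance, so each streak gains at most one
#' detection per frame and leftovers seed new streaks.
#'
#' @param events A data frame of flash detections with columns
#'   `recording_id`, `frame` (0-based integer), `x`, `y`, `z` (meters).
#' @param radius_m Maximum distance (m) between detections at consecutive
#'   frames belonging to the same streak. Default 0.2.
#' @return The events as a tibble, sorted by recording and frame, with an
#'   integer `streak` column identifying the partition.
#' @export
link_streaks <- function(events, radius_m = 0.2) {
  if (!is.numeric(radius_m) || length(radius_m) != 1L || radius_m <= 0) {
    abort("`radius_m` must be a single positive number.")
  }
  events <- as_event_table(events)
  if (nrow(events) == 0L) {
    return(dplyr::mutate(events, streak = integer(0)))
  }
  events <- dplyr::arrange(events, .data$recording_id, .data$frame,
                           .data$x, .data$y, .data$z)
  out <- vector("list", length(unique(events$recording_id)))
  next_id <- 1L
  pieces <- split(events, events$recording_id)
  for (k in seq_along(pieces)) {
    ev <- pieces[[k]]
    ids <- integer(nrow(ev))
    by_frame <- split(seq_len(nrow(ev)), ev$frame)
    frames <- as.integer(names(by_frame))
    active_rows <- integer(0)   # row indices whose streak ended at prev frame
    prev_frame <- NA_integer_
    for (fi in seq_along(frames)) {
      f <- frames[fi]
      rows <- by_frame[[fi]]
      if (is.na(prev_frame) || f != prev_frame + 1L) active_rows <- integer(0)
      taken_ev <- rep(FALSE, length(rows))
      taken_act <- rep(FALSE, length(active_rows))
      if (length(active_rows) > 0L) {
        # pairwise distances active-ends x current detections
        d <- outer(active_rows, rows, function(i, j) {
          sqrt((ev$x[i] - ev$x[j])^2 + (ev$y[i] - ev$y[j])^2 +
                 (ev$z[i] - ev$z[j])^2)
        })
        repeat {
          d_ok <- d
          d_ok[taken_act, ] <- Inf
          d_ok[, taken_ev] <- Inf
          m <- which.min(d_ok)
          if (length(m) == 0L || d_ok[m] > radius_m) break
          ai <- (m - 1L) %% length(active_rows) + 1L
          ei <- (m - 1L) %/% length(active_rows) + 1L
          ids[rows[ei]] <- ids[active_rows[ai]]
          taken_act[ai] <- TRUE
          taken_ev[ei] <- TRUE
          if (all(taken_act) || all(taken_ev)) break
        }
      }
      for (ei in which(!taken_ev)) {
        ids[rows[ei]] <- next_id
        next_id <- next_id + 1L
      }
      active_rows <- rows
      prev_frame <- f
    }
    ev$streak <- ids
    out[[k]] <- ev
  }
  dplyr::bind_rows(out)
}

#' Link streaks into trajectories
#'
#' Streaks whose endpoints occur within both `max_gap_s` seconds and
#' `max_dist_m` meters of each other are assumed to come from the same
#' individual; a trajectory is a set of transitively connected streaks
#' (connected components of the proximity graph). The temporal gap is
#' measured from the end of the earlier-starting streak to the start of the
#' later one, and the spatial distance between those two endpoints.
#'
#' @param streaks A data frame as returned by [link_streaks()] (events with
#'   a `streak` column).
#' @param max_gap_s Maximum time between streak endpoints (s). Default 1.
#' @param max_dist_m Maximum distance between streak endpoints (m). Default 1.
#' @param fps Frames per second. Default 30.
#' @return The events tibble with an added integer `trajectory` column.
#' @export
link_trajectories <- function(streaks, max_gap_s = 1, max_dist_m = 1, fps = 30) {
  if (max_gap_s < 0 || max_dist_m < 0) {
    abort("`max_gap_s` and `max_dist_m` must be non-negative.")
  }
  events <- as_event_table(streaks, require_streak = TRUE)
  if (nrow(events) == 0L) {
    return(dplyr::mutate(events, trajectory = integer(0)))
  }
  ends <- events |>
    dplyr::group_by(.data$recording_id, .data$streak) |>
    dplyr::summarise(
      start_frame = min(.data$frame),
      end_frame = max(.data$frame),
      sx = .data$x[which.min(.data$frame)],
      sy = .data$y[which.min(.data$frame)],
      sz = .data$z[which.min(.data$frame)],
      ex = .data$x[which.max(.data$frame)],
      ey = .data$y[which.max(.data$frame)],
      ez = .data$z[which.max(.data$frame)],
      .groups = "drop"
    )
  n <- nrow(ends)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (rec in unique(ends$recording_id)) {
    idx <- which(ends$recording_id == rec)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        i <- idx[a]; j <- idx[b]
        # order so `first` starts no later than `second`
        if (ends$start_frame[i] <= ends$start_frame[j]) {
          fi <- i; se <- j
        } else {
          fi <- j; se <- i
        }
        gap_s <- (ends$start_frame[se] - ends$end_frame[fi]) / fps
        if (gap_s > max_gap_s) next
        d <- sqrt((ends$ex[fi] - ends$sx[se])^2 +
                    (ends$ey[fi] - ends$sy[se])^2 +
                    (ends$ez[fi] - ends$sz[se])^2)
        if (d <= max_dist_m) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  ends$trajectory <- match(roots, unique(roots))
  key <- paste(events$recording_id, events$streak)
  ekey <- paste(ends$recording_id, ends$streak)
  events$trajectory <- ends$trajectory[match(key, ekey)]
  events
}

#' Extract binary flash sequences from trajectories
#'
#' For each trajectory, bit `i` is 1 iff frame `start_frame + i` contains a
#' flash of that trajectory; the sequence spans the trajectory's first to
#' last flash, so it starts and ends with 1.
#'
#' @param trajectories A data frame as returned by [link_trajectories()]
#'   (events with a `trajectory` column).
#' @param fps Frames per second recorded in the output. Default 30.
#' @return A tibble with one row per trajectory: `recording_id`,
#'   `trajectory`, `start_frame`, `bits`.
#' @export
trajectories_to_sequences <- function(trajectories, fps = 30) {
  events <- as_event_table(trajectories, require_streak = FALSE)
  if (!"trajectory" %in% names(events)) {
    abort("`trajectories` must have a `trajectory` column; see link_trajectories().")
  }
  if (nrow(events) == 0L) {
    return(tibble::tibble(recording_id = character(0), trajectory = integer(0),
                          start_frame = integer(0), bits = character(0)))
  }
  events |>
    dplyr::group_by(.data$recording_id, .data$trajectory) |>
    dplyr::summarise(
      start_frame = min(.data$frame),
      bits = {
        f <- unique(.data$frame) - min(.data$frame)
        v <- integer(max(f) + 1L)
        v[f + 1L] <- 1L
        vec_to_bits(v)
      },
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$recording_id, .data$start_frame)
}

#' Fill spurious short inter-flash gaps
#'
#' Interflash gaps of 1 or 2 bits (less than 0.07 s at 30 fps) are likely
#' tracking errors or brief occlusions, so they are replaced by ones,
#' reconnecting the interrupted flash. Gaps of 3 or more bits are kept.
#' The operation is idempotent and never decreases the number of 1-bits.
#'
#' @param ds A sequence table (data frame with a `bits` column), or a
#'   character vector of 0/1 strings.
#' @param max_fill Longest zero-run to fill, in bits. Default 2.
#' @return Object of the same shape with gaps filled.
#' @export
clean_short_gaps <- function(ds, max_fill = 2) {
  fill1 <- function(bits) {
    v <- bits_to_vec(bits)
    r <- rle(v)
    k <- length(r$lengths)
    interior <- seq_len(k) > 1L & seq_len(k) < k
    r$values[r$values == 0L & r$lengths <= max_fill & interior] <- 1L
    vec_to_bits(inverse.rle(r))
  }
  if (is.character(ds)) {
    assert_bits(ds)
    return(vapply(ds, fill1, character(1), USE.NAMES = FALSE))
  }
  ds <- as_sequence_table(ds)
  ds$bits <- vapply(ds$bits, fill1, character(1), USE.NAMES = FALSE)
  ds
}

#' Drop trajectories containing only one flash
#'
#' Single-flash trajectories are thresholded away to eliminate noise from
#' the trajectory extraction; run after [clean_short_gaps()] so flashes
#' merged by gap filling count as one.
#'
#' @param ds A sequence table.
#' @param min_flashes Minimum number of flash runs to retain. Default 2.
#' @return The filtered sequence table.
#' @export
filter_single_flash <- function(ds, min_flashes = 2) {
  ds <- as_sequence_table(ds)
  ds[count_flash_runs(ds$bits) >= min_flashes, , drop = FALSE]
}

#' Drop species with too few sequences
#'
#' Species represented by fewer than `min_count` trajectories are removed;
#' at least one hundred trajectories per species are needed before patterns
#' can be robustly distinguished.
#'
#' @param ds A labeled sequence table (with a `species` column).
#' @param min_count Minimum sequences per species. Default 100.
#' @return The filtered sequence table.
#' @export
filter_rare_species <- function(ds, min_count = 100) {
  ds <- as_sequence_table(ds, labeled = TRUE)
  ds |>
    dplyr::group_by(.data$species) |>
    dplyr::filter(dplyr::n() >= min_count) |>
    dplyr::ungroup()
}

#' Per-sequence flash statistics
#'
#' Computes, for each sequence, the number of flashes (maximal runs of 1s),
#' the duration of each flash, and each inter-flash gap -- the dark period
#' from the end of one flash to the start of the next (distinct from the
#' inter-flash interval, which is start-to-start). Durations are in seconds
#' (`frames / fps`).
#'
#' @param ds A sequence table, or a character vector of 0/1 strings.
#' @param fps Frames per second. Default 30.
#' @return A tibble with the input columns plus `n_flashes`,
#'   `flash_durations_s` and `gaps_s` (list-columns of per-event values),
#'   and convenience means `mean_duration_s` and `mean_gap_s` (`NA` for a
#'   single-flash sequence, whose gap is undefined).
#' @export
sequence_stats <- function(ds, fps = 30) {
  if (is.character(ds)) ds <- tibble::tibble(bits = ds)
  ds <- as_sequence_table(ds)
  vs <- bits_to_vecs(ds$bits)
  per <- lapply(vs, function(v) {
    v <- trim_to_flashes(v)
    r <- rle(v)
    list(dur = r$lengths[r$values == 1L] / fps,
         gap = r$lengths[r$values == 0L] / fps)
  })
  ds$n_flashes <- vapply(per, function(p) length(p$dur), integer(1))
  ds$flash_durations_s <- lapply(per, function(p) p$dur)
  ds$gaps_s <- lapply(per, function(p) p$gap)
  ds$mean_duration_s <- vapply(per, function(p) mean(p$dur), numeric(1))
  ds$mean_gap_s <- vapply(per, function(p) {
    if (length(p$gap) == 0L) NA_real_ else mean(p$gap)
  }, numeric(1))
  ds
}

#' Label encoding for a sequence table
#'
#' Species names are transformed into machine-readable integer codes; the
#' mapping is a bijection over the species present, in sorted name order.
#'
#' @param ds A labeled sequence table.
#' @return A tibble with columns `species` and `code` (1-based integers).
#' @export
make_label_map <- function(ds) {
  ds <- as_sequence_table(ds, labeled = TRUE)
  sp <- sort(unique(ds$species))
  tibble::tibble(species = sp, code = seq_along(sp))
}

# ---- internal validators ----------------------------------------------------

as_event_table <- function(events, require_streak = FALSE) {
  need <- c("recording_id", "frame", "x", "y", "z")
  if (require_streak) need <- c(need, "streak")
  if (!is.data.frame(events) || !all(need %in% names(events))) {
    abort(paste0("expected a data frame with columns ",
                 paste(need, collapse = ", "), "."))
  }
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0L) {
    if (any(events$frame < 0)) abort("`frame` indices must be >= 0.")
    if (!all(is.finite(events$x) & is.finite(events$y) & is.finite(events$z))) {
      abort("event positions must be finite.")
    }
  }
  events$frame <- as.integer(events$frame)
  events
}

as_sequence_table <- function(ds, labeled = FALSE) {
  if (!is.data.frame(ds) || !"bits" %in% names(ds)) {
    abort("expected a data frame with a `bits` column of 0/1 strings.")
  }
  if (labeled && !"species" %in% names(ds)) {
    abort("expected a labeled sequence table with a `species` column.")
  }
  ds <- tibble::as_tibble(ds)
  if (nrow(ds) > 0L) assert_bits(ds$bits)
  ds
}
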