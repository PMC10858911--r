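#' Jaccard score between a sequence and a reference
#'
#' For sequences `(a_m)` and `(b_n)` of lengths `M` and `N`, the
#' intersection is `sum_{i=1..min(M,N)} a_i * b_i` (the on-mass occurring
#' simultaneously in both) and the union is `sum(a) + sum(b)` (the combined
#' on-mass). The score is intersection / union. Because the union is the
#' summed mass rather than the set union, two identical binary sequences
#' score 0.5, not 1, and 0.5 is the maximum for binary inputs. A reference
#' may be real-valued in \[0, 1\] (population references); the same sums
#' apply.
#'
#' @param a,b Numeric vectors (binary sequence and reference, either order).
#' @return A single score in \[0, 0.5\] for binary inputs; 0 when both
#'   sequences are all-zero.
#' @export
jaccard_score <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("sequences must be non-empty.")
  un <- sum(a) + sum(b)
  if (un == 0) return(0)
  dot_score(a, b) / un
}

#' Dot product score between a sequence and a reference
#'
#' The sum of the elementwise product over the first `min(M, N)` elements.
#'
#' @inheritParams jaccard_score
#' @return A single non-negative score.
#' @export
dot_score <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("sequences must be non-empty.")
  k <- min(length(a), length(b))
  sum(a[seq_len(k)] * b[seq_len(k)])
}

#' Dynamic time warping distance
#'
#' Classic full-path dynamic time warping with local cost `|a_i - b_j|` and
#' steps (1,0), (0,1), (1,1); no window constraint. DTW locally stretches or
#' compresses the sequences to optimize the match, so it is robust to
#' variation in flash timing. Symmetric, and 0 for identical inputs.
#'
#' @inheritParams jaccard_score
#' @return The DTW distance (non-negative).
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) abort("sequences must be non-empty.")
  n <- length(a); m <- length(b)
  prev <- c(0, rep(Inf, m))
  cur <- numeric(m + 1L)
  for (i in seq_len(n)) {
    cur[1] <- Inf
    ci <- abs(a[i] - b)
    for (j in seq_len(m)) {
      cur[j + 1L] <- ci[j] + min(prev[j], prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Numerically stable softmax
#'
#' `p_k = exp(s_k) / sum_j exp(s_j)`, computed with max-subtraction so it is
#' invariant to constant shifts and safe for large scores.
#'
#' @param scores A finite numeric vector.
#' @return A probability vector summing to 1 (names preserved).
#' @export
softmax <- function(scores) {
  if (any(!is.finite(scores))) abort("`scores` must be finite.")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Classify sequences against per-species references
#'
#' Computes one score per candidate species with the chosen metric, turns
#' the score vector into probabilities with [softmax()], and predicts the
#' arg max. DTW is a distance, so distances are negated before the softmax
#' (smaller distance, higher probability); Jaccard and dot scores are
#' similarities and enter as-is. Ties are broken by species label order.
#'
#' @param ds A sequence table or character vector of 0/1 strings.
#' @param refs A reference table as returned by [literature_references()] or
#'   [population_references()]: columns `species` and `values`.
#' @param metric One of `"jaccard"`, `"dot"`, `"dtw"`.
#' @return A tibble with one row per sequence: `predicted` (species label),
#'   `confidence` (maximum probability) and `probs` (list-column of named
#'   probability vectors summing to 1).
#' @export
classify_by_reference <- function(ds, refs, metric = c("jaccard", "dot", "dtw")) {
  metric <- rlang::arg_match(metric)
  if (!is.data.frame(refs) || !all(c("species", "values") %in% names(refs))) {
    abort("`refs` must be a data frame with `species` and `values` columns.")
  }
  if (nrow(refs) < 2L) abort("need at least 2 references to classify.")
  refs <- dplyr::arrange(refs, .data$species)
  if (is.character(ds)) ds <- tibble::tibble(bits = ds)
  ds <- as_sequence_table(ds)
  score_fn <- switch(metric,
    jaccard = jaccard_score,
    dot = dot_score,
    dtw = function(a, b) -dtw_distance(a, b)
  )
  vs <- bits_to_vecs(ds$bits)
  probs <- lapply(vs, function(v) {
    s <- vapply(refs$values, function(r) score_fn(v, r), numeric(1))
    setNames(softmax(s), refs$species)
  })
  tibble::tibble(
    predicted = vapply(probs, function(p) names(p)[which.max(p)], character(1)),
    confidence = vapply(probs, max, numeric(1)),
    probs = probs
  )
}
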