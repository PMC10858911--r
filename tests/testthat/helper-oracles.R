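# Independent oracles, deliberately implemented differently from the package.

# All monotone warping paths from (1,1) to (M,N) with steps (1,0),(0,1),(1,1),
# as k x 2 index matrices. Enumerated recursively, once per shape.
enumerate_warping_paths <- function(M, N) {
  recurse <- function(i, j) {
    if (i == M && j == N) return(list(matrix(c(i, j), 1L, 2L)))
    out <- list()
    for (step in list(c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
      ni <- i + step[1]; nj <- j + step[2]
      if (ni <= M && nj <= N) {
        out <- c(out, lapply(recurse(ni, nj),
                             function(p) rbind(c(i, j), p)))
      }
    }
    out
  }
  recurse(1L, 1L)
}

# Minimum path cost for every pair of rows of A (n_a x M) and B (n_b x N):
# brute force over all enumerated paths, vectorized over the pair grid.
oracle_dtw_all_pairs <- function(A, B) {
  paths <- enumerate_warping_paths(ncol(A), ncol(B))
  best <- matrix(Inf, nrow(A), nrow(B))
  for (p in paths) {
    cost <- matrix(0, nrow(A), nrow(B))
    for (k in seq_len(nrow(p))) {
      cost <- cost + abs(outer(A[, p[k, 1]], B[, p[k, 2]], "-"))
    }
    best <- pmin(best, cost)
  }
  best
}

all_binary_rows <- function(m) {
  as.matrix(expand.grid(rep(list(c(0, 1)), m)))
}

# Plain per-class tally of precision/recall/accuracy.
oracle_weighted_metrics <- function(predicted, truth) {
  classes <- sort(unique(truth))
  tp <- fp <- fn <- setNames(numeric(length(classes)), classes)
  for (i in seq_along(truth)) {
    if (predicted[i] == truth[i]) {
      tp[truth[i]] <- tp[truth[i]] + 1
    } else {
      fn[truth[i]] <- fn[truth[i]] + 1
      if (predicted[i] %in% classes) fp[predicted[i]] <- fp[predicted[i]] + 1
    }
  }
  support <- tp + fn
  prec <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec <- tp / support
  list(precision = sum(support / sum(support) * prec),
       recall = sum(support / sum(support) * rec),
       accuracy = sum(tp) / length(truth))
}
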