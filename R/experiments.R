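#' Stratified cross-validation folds with class-balancing undersampling
#'
#' Builds `k` folds, each splitting the data into ninety percent training
#' and ten percent testing while preserving the class ratios of the full
#' dataset. Test membership cycles through `1/test_frac` disjoint stratified
#' bins, so across folds every sequence is used at least once in testing and
#' never appears in training and testing simultaneously within a fold.
#' Because of severe class imbalance, the training portion is randomly
#' undersampled (without replacement, seeded) to equalize class counts; a
#' validation set is carved from the equalized pool, and all remaining data
#' join the test pool.
#'
#' @param ds A labeled sequence table; every class must have at least `k`
#'   sequences.
#' @param k Number of folds. Default 60.
#' @param test_frac Fraction of each class held out as the raw test split.
#'   Default 0.1.
#' @param val_frac Fraction of the equalized pool used for validation.
#'   Default 0.1.
#' @param seed Integer seed.
#' @return A tibble with one row per fold and list-columns of row indices
#'   into `ds`: `train`, `val`, `test` (raw split plus undersampling
#'   leftovers) and `raw_test` (the stratified ten percent alone).
#' @export
stratified_folds <- function(ds, k = 60, test_frac = 0.1, val_frac = 0.1,
                             seed = 1L) {
  ds <- as_sequence_table(ds, labeled = TRUE)
  counts <- table(ds$species)
  if (any(counts < k)) {
    abort(sprintf("every class needs >= %d sequences; smallest has %d.",
                  k, min(counts)))
  }
  n_bins <- as.integer(round(1 / test_frac))
  withr::with_seed(seed, {
    cls_idx <- split(seq_len(nrow(ds)), ds$species)
    bins <- lapply(cls_idx, function(ix) {
      perm <- sample(ix)
      split(perm, rep_len(seq_len(n_bins), length(perm)))
    })
    folds <- vector("list", k)
    for (f in seq_len(k)) {
      tb <- (f - 1L) %% n_bins + 1L
      raw_test <- unlist(lapply(bins, function(b) b[[tb]]), use.names = FALSE)
      raw_train <- lapply(bins, function(b) {
        unlist(b[-tb], use.names = FALSE)
      })
      m <- min(lengths(raw_train))
      pool <- lapply(raw_train, function(ix) sample(ix, m))
      leftover <- unlist(
        purrr::map2(raw_train, pool, setdiff), use.names = FALSE)
      n_val <- ceiling(val_frac * m)
      val <- lapply(pool, function(ix) sample(ix, n_val))
      train <- unlist(purrr::map2(pool, val, setdiff), use.names = FALSE)
      folds[[f]] <- tibble::tibble(
        fold = f,
        train = list(sort(train)),
        val = list(sort(unlist(val, use.names = FALSE))),
        test = list(sort(c(raw_test, leftover))),
        raw_test = list(sort(raw_test))
      )
    }
    dplyr::bind_rows(folds)
  })
}

#' Seeded random undersampling to equal class counts
#'
#' @param ds A labeled sequence table.
#' @param seed Integer seed.
#' @return The subset of `ds` with every class downsampled (without
#'   replacement) to the minority-class count.
#' @export
undersample_equalize <- function(ds, seed = 1L) {
  ds <- as_sequence_table(ds, labeled = TRUE)
  m <- min(table(ds$species))
  withr::with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(ds)), ds$species),
                          function(ix) sample(ix, m)), use.names = FALSE)
    ds[sort(keep), , drop = FALSE]
  })
}

#' Weighted precision, recall and accuracy
#'
#' Per-class precision and recall averaged with weights equal to the class
#' support (true-label counts); accuracy is the fraction of correct
#' predictions. A class that is never predicted contributes precision 0.
#'
#' @param predicted,truth Equal-length vectors of class labels.
#' @return A one-row tibble with `precision`, `recall`, `accuracy`.
#' @export
weighted_metrics <- function(predicted, truth) {
  if (length(predicted) == 0L || length(predicted) != length(truth)) {
    abort("`predicted` and `truth` must be equal-length, non-empty.")
  }
  classes <- sort(unique(truth))
  support <- vapply(classes, function(cl) sum(truth == cl), numeric(1))
  prec <- vapply(classes, function(cl) {
    np <- sum(predicted == cl)
    if (np == 0) 0 else sum(predicted == cl & truth == cl) / np
  }, numeric(1))
  rec <- vapply(classes, function(cl) {
    sum(predicted == cl & truth == cl) / sum(truth == cl)
  }, numeric(1))
  w <- support / sum(support)
  tibble::tibble(
    precision = sum(w * prec),
    recall = sum(w * rec),
    accuracy = mean(predicted == truth)
  )
}

#' Row-normalized confusion matrix
#'
#' Rows are true classes, columns predicted classes; with row normalization
#' the diagonal is the per-class recall (ratio of true positives along each
#' row).
#'
#' @param predicted,truth Equal-length label vectors.
#' @param normalize `"row"` (default) or `"none"`.
#' @return A numeric matrix with classes as dimnames.
#' @export
confusion_matrix <- function(predicted, truth, normalize = c("row", "none")) {
  normalize <- rlang::arg_match(normalize)
  classes <- sort(unique(c(predicted, truth)))
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.numeric(m), nrow = length(classes),
              dimnames = list(truth = classes, predicted = classes))
  if (normalize == "row") {
    rs <- rowSums(m)
    m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  m
}

#' One-vs-rest ROC curves and AUC per species
#'
#' For each species, its predicted probability is used as the score for the
#' binary task "is this species vs. is not", sweeping all thresholds. A
#' species with no positive (or no negative) examples has an undefined curve
#' and is reported with `NA` AUC and an empty curve.
#'
#' @param preds A prediction tibble with a `probs` list-column (from
#'   [predict.fireflash_gru()], [classify_by_reference()] or
#'   [predict.fireflash_svm()]).
#' @param truth True species labels, one per row of `preds`.
#' @return A tibble with one row per species: `species`, `auc` and `curve`
#'   (list-column of tibbles with `fpr`, `tpr` sorted along the threshold
#'   sweep).
#' @export
roc_curves <- function(preds, truth) {
  if (!is.data.frame(preds) || !"probs" %in% names(preds)) {
    abort("`preds` must be a prediction tibble with a `probs` list-column.")
  }
  species <- sort(unique(names(preds$probs[[1]])))
  purrr::map_dfr(species, function(sp) {
    score <- vapply(preds$probs, function(p) unname(p[sp]), numeric(1))
    pos <- truth == sp
    if (all(pos) || !any(pos)) {
      return(tibble::tibble(
        species = sp, auc = NA_real_,
        curve = list(tibble::tibble(fpr = numeric(0), tpr = numeric(0)))
      ))
    }
    r <- pROC::roc(response = pos, predictor = score,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
    curve <- tibble::tibble(fpr = rev(1 - r$specificities),
                            tpr = rev(r$sensitivities))
    tibble::tibble(species = sp, auc = as.numeric(pROC::auc(r)),
                   curve = list(curve))
  })
}
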