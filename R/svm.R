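#' Three-parameter feature representation of flash sequences
#'
#' Each flash sequence is parametrized by the number of flashes, the average
#' flash duration (s), and the average inter-flash gap (s). Sequences must
#' be cleaned and contain at least two flashes (the gap is undefined
#' otherwise).
#'
#' @param ds A sequence table or character vector of 0/1 strings.
#' @param fps Frames per second. Default 30.
#' @return A tibble with columns `n_flashes`, `mean_duration_s`,
#'   `mean_gap_s`.
#' @export
svm_features <- function(ds, fps = 30) {
  st <- sequence_stats(ds, fps = fps)
  if (any(st$n_flashes < 2L)) {
    abort("all sequences must contain at least 2 flashes; run clean_short_gaps() and filter_single_flash() first.")
  }
  st[, c("n_flashes", "mean_duration_s", "mean_gap_s")]
}

#' Train a radial-basis SVM on flash-pattern features
#'
#' Fits a support vector machine with a radial basis kernel in the
#' 3-dimensional space of (flash count, mean flash duration, mean
#' inter-flash gap). Features are standardized to zero mean and unit
#' variance on the training split; class probabilities come from the
#' fitted probability model (pairwise coupling).
#'
#' @param ds A labeled, cleaned sequence table with >= 2 species.
#' @param cost Regularization constant. Default 1.
#' @param gamma Kernel width; default `1 / 3` (one over the feature count,
#'   on standardized features).
#' @param fps Frames per second. Default 30.
#' @param seed Optional integer seed for the internal probability-model
#'   cross-validation.
#' @return An object of class `fireflash_svm`.
#' @export
train_svm <- function(ds, cost = 1, gamma = 1 / 3, fps = 30, seed = NULL) {
  ds <- as_sequence_table(ds, labeled = TRUE)
  if (length(unique(ds$species)) < 2L) {
    abort("need at least 2 species to train a classifier.")
  }
  feats <- svm_features(ds, fps = fps)
  x <- as.matrix(feats)
  y <- factor(ds$species, levels = sort(unique(ds$species)))
  fit_call <- function() {
    e1071::svm(x = x, y = y, kernel = "radial", cost = cost, gamma = gamma,
               scale = TRUE, probability = TRUE)
  }
  fit <- if (is.null(seed)) fit_call() else withr::with_seed(seed, fit_call())
  structure(
    list(fit = fit, species = levels(y), fps = fps,
         cost = cost, gamma = gamma, n_train = nrow(ds)),
    class = "fireflash_svm"
  )
}

#' Predict species from a fitted flash-pattern SVM
#'
#' @param object A `fireflash_svm` model.
#' @param ds A cleaned sequence table (or 0/1 strings).
#' @param ... Unused.
#' @return A tibble with `predicted`, `confidence` and `probs` columns, as
#'   for [classify_by_reference()].
#' @export
predict.fireflash_svm <- function(object, ds, ...) {
  feats <- svm_features(ds, fps = object$fps)
  pr <- predict(object$fit, as.matrix(feats), probability = TRUE)
  pm <- attr(pr, "probabilities")[, object$species, drop = FALSE]
  probs <- lapply(seq_len(nrow(pm)), function(i) pm[i, ])
  tibble::tibble(
    predicted = vapply(probs, function(p) names(p)[which.max(p)], character(1)),
    confidence = vapply(probs, max, numeric(1)),
    probs = probs
  )
}

#' @export
print.fireflash_svm <- function(x, ...) {
  cat("<fireflash_svm> radial-basis SVM on (n_flashes, mean_duration_s, mean_gap_s)\n")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat(sprintf("  trained on %d sequences; cost = %g, gamma = %g\n",
              x$n_train, x$cost, x$gamma))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.fireflash_svm <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_species = length(x$species),
    n_support_vectors = nrow(x$fit$SV),
    cost = x$cost,
    gamma = x$gamma
  )
}
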