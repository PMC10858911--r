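#' Train the GRU flash-pattern classifier
#'
#' Trains a gated recurrent network on binarized flash sequences, fed one
#' bit per timestep (no handcrafted features), with the Adam optimizer on
#' the cross-entropy loss, global gradient-norm clipping, and early stopping
#' that monitors the validation loss with the configured patience. The
#' parameters from the best-validation-loss epoch are returned. Class counts
#' should be equalized upstream (see [stratified_folds()]); no data
#' augmentation is applied.
#'
#' @param train,val Labeled sequence tables sharing one species set.
#' @param config A [gru_config()]; its `seed` governs initialization and
#'   shuffling, so identical inputs and config give identical models.
#' @return An object of class `fireflash_gru` with elements `config`,
#'   `params`, `label_map`, `history` (per-epoch train/validation loss) and
#'   `best_epoch`.
#' @export
train_gru <- function(train, val, config) {
  train <- as_sequence_table(train, labeled = TRUE)
  val <- as_sequence_table(val, labeled = TRUE)
  if (nrow(train) == 0L || nrow(val) == 0L) {
    abort("`train` and `val` must be non-empty.")
  }
  if (!inherits(config, "gru_config")) abort("`config` must be a gru_config().")
  sp <- sort(unique(c(train$species, val$species)))
  lm <- tibble::tibble(species = sp, code = seq_along(sp))
  if (nrow(lm) != config$n_species) {
    abort(sprintf("config says %d species but data contain %d.",
                  config$n_species, nrow(lm)))
  }
  tr_seqs <- bits_to_vecs(train$bits)
  tr_lab <- match(train$species, lm$species)
  va_seqs <- bits_to_vecs(val$bits)
  va_lab <- match(val$species, lm$species)

  withr::with_seed(config$seed, {
    params <- gru_init_params(config)
    state <- adam_init(params)
    best <- list(loss = Inf, params = params, epoch = 0L)
    wait <- 0L
    history <- vector("list", config$max_epochs)
    n <- length(tr_seqs)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0
      for (bi in batches) {
        bp <- gru_gradients(params, config, tr_seqs[bi], tr_lab[bi])
        g <- clip_gradients(bp$grads, config$grad_clip_norm)
        upd <- adam_step(params, g, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        ep_loss <- ep_loss + bp$loss * length(bi)
      }
      ep_loss <- ep_loss / n
      val_loss <- eval_loss(params, config, va_seqs, va_lab)
      history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val_loss)
      if (val_loss < best$loss - 1e-10) {
        best <- list(loss = val_loss, params = params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$early_stop_patience) break
      }
    }
    structure(
      list(config = config, params = best$params, label_map = lm,
           history = dplyr::bind_rows(history), best_epoch = best$epoch,
           best_val_loss = best$loss),
      class = "fireflash_gru"
    )
  })
}

# Forward-only mean loss over a dataset, evaluated in chunks.
eval_loss <- function(params, cfg, seqs, labels, chunk = 64L) {
  n <- length(seqs)
  idx <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  tot <- 0
  for (bi in idx) {
    tot <- tot + gru_loss(params, cfg, seqs[bi], labels[bi]) * length(bi)
  }
  tot / n
}

#' Forward pass of the GRU on a single sequence
#'
#' Runs the recurrence over all timesteps of one sequence and returns the
#' hidden trajectory of the last recurrent layer together with the readout.
#'
#' @param model A trained `fireflash_gru`.
#' @param bits A single 0/1 string or numeric 0/1 vector.
#' @return A list with `hidden` (T x hidden_dim matrix of last-layer hidden
#'   states), `logits` and `probabilities` (named, summing to 1).
#' @export
gru_forward <- function(model, bits) {
  stopifnot(inherits(model, "fireflash_gru"))
  v <- if (is.character(bits)) bits_to_vec(assert_bits(bits)) else as.numeric(bits)
  if (length(v) == 0L) abort("`bits` must be non-empty.")
  fwd <- gru_forward_batch(model$params, model$config, list(v), cache = TRUE)
  L <- model$config$n_layers
  hidden <- t(vapply(fwd$Hout[[L]], function(h) h[, 1L],
                     numeric(model$config$hidden_dim)))
  list(
    hidden = hidden,
    logits = setNames(fwd$logits[, 1L], model$label_map$species),
    probabilities = setNames(fwd$probs[, 1L], model$label_map$species)
  )
}

#' Predict species with a trained GRU
#'
#' Deterministic batched inference; labels present in `ds` are ignored
#' (they are only used downstream for evaluation).
#'
#' @param object A trained `fireflash_gru`.
#' @param ds A sequence table or character vector of 0/1 strings.
#' @param batch_size Inference batch size. Default 64.
#' @param ... Unused.
#' @return A tibble with `predicted`, `confidence` and `probs`, one row per
#'   sequence, as for [classify_by_reference()].
#' @export
predict.fireflash_gru <- function(object, ds, batch_size = 64L, ...) {
  if (is.character(ds)) ds <- tibble::tibble(bits = ds)
  ds <- as_sequence_table(ds)
  seqs <- bits_to_vecs(ds$bits)
  sp <- object$label_map$species
  n <- length(seqs)
  probs <- vector("list", n)
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fwd <- gru_forward_batch(object$params, object$config, seqs[bi])
    for (k in seq_along(bi)) probs[[bi[k]]] <- setNames(fwd$probs[, k], sp)
  }
  tibble::tibble(
    predicted = vapply(probs, function(p) names(p)[which.max(p)], character(1)),
    confidence = vapply(probs, max, numeric(1)),
    probs = probs
  )
}

#' Final hidden-state embedding of sequences
#'
#' Returns the final-timestep hidden state of the last recurrent layer for
#' each sequence -- the representation just before the readout, used for
#' t-SNE visualization of species clustering.
#'
#' @param model A trained `fireflash_gru`.
#' @param ds A sequence table or character vector of 0/1 strings.
#' @param batch_size Inference batch size. Default 64.
#' @return A numeric matrix, one row per sequence, `hidden_dim` columns.
#' @export
hidden_embedding <- function(model, ds, batch_size = 64L) {
  stopifnot(inherits(model, "fireflash_gru"))
  if (is.character(ds)) ds <- tibble::tibble(bits = ds)
  ds <- as_sequence_table(ds)
  seqs <- bits_to_vecs(ds$bits)
  n <- length(seqs)
  out <- matrix(NA_real_, n, model$config$hidden_dim)
  for (bi in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    fwd <- gru_forward_batch(model$params, model$config, seqs[bi])
    out[bi, ] <- t(fwd$hfin)
  }
  out
}

#' Save / load a GRU model checkpoint
#'
#' The checkpoint is a single-file archive holding a format version, the
#' config, label map, parameter tensors and training history.
#'
#' @param model A trained `fireflash_gru`.
#' @param path Checkpoint path.
#' @return `write_checkpoint()` returns `model` invisibly;
#'   `read_checkpoint()` returns the restored `fireflash_gru`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "fireflash_gru"))
  saveRDS(list(format = "fireflash_gru_checkpoint", version = 1L,
               model = unclass(model)), path)
  invisible(model)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "fireflash_gru_checkpoint")) {
    abort("not a fireflash GRU checkpoint.")
  }
  if (ck$version > 1L) abort("checkpoint written by a newer format version.")
  structure(ck$model, class = "fireflash_gru")
}

#' @export
print.fireflash_gru <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<fireflash_gru> %d-layer GRU, %d hidden units, %d species\n",
              cfg$n_layers, cfg$hidden_dim, cfg$n_species))
  cat(sprintf("  trained %d epochs (best epoch %d, val loss %.4f)\n",
              nrow(x$history), x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.fireflash_gru <- function(x, ...) {
  x$history
}

#' @exportS3Method generics::glance
glance.fireflash_gru <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    n_species = x$config$n_species,
    hidden_dim = x$config$hidden_dim,
    n_layers = x$config$n_layers
  )
}
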