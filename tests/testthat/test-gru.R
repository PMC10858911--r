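tiny_cfg <- function(seed = 7L) {
  gru_config(n_species = 3, n_layers = 2, hidden_dim = 4, seed = seed)
}

test_that("analytic BPTT gradients match numerical differentiation", {
  cfg <- tiny_cfg()
  params <- withr::with_seed(1, fireflash:::gru_init_params(cfg))
  seqs <- list(c(1, 0, 1, 1, 0), c(1, 1, 0), c(1, 0, 0, 0, 1, 1, 1))
  labels <- c(1L, 2L, 3L)
  bp <- fireflash:::gru_gradients(params, cfg, seqs, labels)
  eps <- 1e-6
  withr::with_seed(42, {
    for (nm in names(params)) {
      for (i in head(sample(seq_along(params[[nm]])), 6)) {
        up <- params; up[[nm]][i] <- up[[nm]][i] + eps
        dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
        num <- (fireflash:::gru_loss(up, cfg, seqs, labels) -
                  fireflash:::gru_loss(dn, cfg, seqs, labels)) / (2 * eps)
        expect_equal(bp$grads[[nm]][i], num, tolerance = 1e-5)
      }
    }
  })
})

test_that("padded batched forward equals per-sequence forward", {
  cfg <- tiny_cfg()
  params <- withr::with_seed(3, fireflash:::gru_init_params(cfg))
  seqs <- list(c(1), c(1, 0, 1), c(1, 0, 0, 0, 1, 1, 1, 0, 1))
  batched <- fireflash:::gru_forward_batch(params, cfg, seqs)
  for (k in seq_along(seqs)) {
    single <- fireflash:::gru_forward_batch(params, cfg, seqs[k])
    expect_equal(batched$probs[, k], single$probs[, 1], tolerance = 1e-5)
    expect_equal(batched$hfin[, k], single$hfin[, 1], tolerance = 1e-5)
  }
})

test_that("zero readout weights give uniform probabilities; probs sum to 1", {
  cfg <- tiny_cfg()
  params <- withr::with_seed(4, fireflash:::gru_init_params(cfg))
  params$V <- params$V * 0
  params$cb <- params$cb * 0
  fwd <- fireflash:::gru_forward_batch(params, cfg, list(c(1, 0, 1)))
  expect_equal(fwd$probs[, 1], rep(1 / 3, 3))
  params2 <- withr::with_seed(5, fireflash:::gru_init_params(cfg))
  fwd2 <- fireflash:::gru_forward_batch(
    params2, cfg, list(c(1, 1, 0), c(1, 0, 0, 1)))
  expect_equal(colSums(fwd2$probs), c(1, 1))
})

test_that("gradient clipping bounds the global norm", {
  g <- list(a = matrix(3, 2, 2), b = rep(-4, 3))
  clipped <- fireflash:::clip_gradients(g, 0.1)
  expect_lte(fireflash:::grad_global_norm(clipped), 0.1 + 1e-12)
  small <- list(a = matrix(0.01, 2, 2))
  expect_equal(fireflash:::clip_gradients(small, 0.1), small)
})

test_that("training is seeded-deterministic, keeps the best checkpoint, loss finite", {
  train <- two_species_dataset(16, seed = 61)
  val <- two_species_dataset(6, seed = 62)
  cfg <- gru_config(n_species = 2, n_layers = 1, hidden_dim = 8,
                    learning_rate = 0.01, grad_clip_norm = 1,
                    early_stop_patience = 3, max_epochs = 6, seed = 5)
  m1 <- train_gru(train, val, cfg)
  m2 <- train_gru(train, val, cfg)
  expect_equal(m1$params, m2$params)
  expect_true(all(is.finite(m1$history$train_loss)))
  expect_true(all(is.finite(m1$history$val_loss)))
  # returned parameters are the best-validation-loss checkpoint
  expect_equal(m1$best_val_loss, min(m1$history$val_loss))
  expect_lte(m1$best_val_loss, m1$history$val_loss[nrow(m1$history)])

  p1 <- predict(m1, val)
  expect_equal(predict(m1, val), p1)       # inference determinism
  expect_equal(nrow(p1), nrow(val))
  for (p in p1$probs) expect_equal(sum(p), 1, tolerance = 1e-9)

  # checkpoint round trip preserves behavior
  path <- withr::local_tempfile(fileext = ".ckpt")
  write_checkpoint(m1, path)
  expect_equal(predict(read_checkpoint(path), val), p1)

  # single-sequence forward agrees with predict
  f <- gru_forward(m1, val$bits[1])
  expect_equal(unname(f$probabilities), unname(p1$probs[[1]]),
               tolerance = 1e-9)
  expect_equal(dim(f$hidden), c(nchar(val$bits[1]), 8))

  # hidden embedding: final state per sequence, identical inputs give
  # identical rows
  emb <- hidden_embedding(m1, val$bits[c(1, 1, 2)])
  expect_equal(dim(emb), c(3, 8))
  expect_equal(emb[1, ], emb[2, ])
  expect_equal(emb[1, ], f$hidden[nrow(f$hidden), ])
})

test_that("config validation enforces the protocol", {
  expect_error(gru_config(1), ">= 2")
  expect_error(gru_config(3, dropout = 0.5), "dropout")
  cfg <- gru_config(3)
  expect_equal(cfg$hidden_dim, 128L)
  expect_equal(cfg$n_layers, 2L)
  expect_equal(cfg$batch_size, 8L)
  expect_equal(cfg$learning_rate, 1e-5)
  expect_equal(cfg$early_stop_patience, 50L)
  expect_equal(cfg$grad_clip_norm, 0.1)
})
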