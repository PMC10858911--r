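# Gated recurrent unit (GRU) classifier, implemented from scratch in matrix
# code: batched forward pass with right-padding masks, backpropagation
# through time, Adam updates with global-norm gradient clipping.
#
# Gate equations per layer (the standard GRU):
#   r = sigmoid(W_ir x + b_ir + W_hr h + b_hr)      reset gate
#   z = sigmoid(W_iz x + b_iz + W_hz h + b_hz)      update gate
#   n = tanh(W_in x + b_in + r * (W_hn x + b_hn))   candidate state
#   h' = (1 - z) * n + z * h
# The three gates are stacked row-wise in Wi (3H x I), Wh (3H x H), bi, bh.
# Padding is handled by a per-timestep mask m in {0,1}^B: h <- m*h' + (1-m)*h,
# so the hidden state of a finished sequence is frozen and the state at the
# final padded timestep equals the state at the sequence's own last frame.
#
# Readout: LeakyReLU(negative slope 0.1) on the final hidden state of the
# last layer, then a single affine map to the species logits, then softmax.

#' GRU classifier configuration
#'
#' Defaults are the architecture and training protocol used throughout:
#' a 2-layer GRU with 128-dimension hidden layers, no dropout, LeakyReLU
#' activation with negative slope 0.1 before the readout, batch size 8,
#' learning rate 1e-5 (Adam), early stopping on the validation loss with a
#' patience of 50 epochs, and gradient clipping of the global norm at 0.1.
#' An epoch cap (`max_epochs`) bounds training. Smaller hidden sizes and
#' larger learning rates are useful for quick experiments on synthetic data.
#'
#' @param n_species Number of output classes (required).
#' @param n_layers Number of stacked GRU layers. Default 2.
#' @param hidden_dim Hidden state dimension. Default 128.
#' @param dropout Dropout rate; only 0 is supported. Default 0.
#' @param activation_negative_slope LeakyReLU negative slope. Default 0.1.
#' @param batch_size Training batch size. Default 8.
#' @param learning_rate Adam learning rate. Default 1e-5.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping. Default 50.
#' @param grad_clip_norm Global gradient-norm clip. Default 0.1.
#' @param max_epochs Hard cap on training epochs. Default 1000.
#' @param seed Master seed governing parameter initialization and shuffling.
#' @return A `gru_config` list.
#' @export
gru_config <- function(n_species,
                       n_layers = 2,
                       hidden_dim = 128,
                       dropout = 0,
                       activation_negative_slope = 0.1,
                       batch_size = 8,
                       learning_rate = 1e-5,
                       early_stop_patience = 50,
                       grad_clip_norm = 0.1,
                       max_epochs = 1000,
                       seed = 1L) {
  if (missing(n_species) || n_species < 2) abort("`n_species` must be >= 2.")
  if (dropout != 0) abort("only `dropout = 0` is supported.")
  stopifnot(n_layers >= 1, hidden_dim >= 1, batch_size >= 1,
            learning_rate > 0, early_stop_patience >= 1,
            grad_clip_norm > 0, max_epochs >= 1)
  structure(
    list(n_species = as.integer(n_species), n_layers = as.integer(n_layers),
         hidden_dim = as.integer(hidden_dim), dropout = dropout,
         activation_negative_slope = activation_negative_slope,
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         early_stop_patience = as.integer(early_stop_patience),
         grad_clip_norm = grad_clip_norm, max_epochs = as.integer(max_epochs),
         seed = as.integer(seed)),
    class = "gru_config"
  )
}

# Uniform(-1/sqrt(H), 1/sqrt(H)) initialization for all parameters.
gru_init_params <- function(cfg) {
  H <- cfg$hidden_dim
  u <- 1 / sqrt(H)
  rmat <- function(r, c) matrix(runif(r * c, -u, u), r, c)
  p <- list()
  for (l in seq_len(cfg$n_layers)) {
    I <- if (l == 1L) 1L else H
    p[[paste0("Wi", l)]] <- rmat(3L * H, I)
    p[[paste0("Wh", l)]] <- rmat(3L * H, H)
    p[[paste0("bi", l)]] <- runif(3L * H, -u, u)
    p[[paste0("bh", l)]] <- runif(3L * H, -u, u)
  }
  p$V <- rmat(cfg$n_species, H)
  p$cb <- runif(cfg$n_species, -u, u)
  p
}

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope) {
  neg <- x < 0
  x[neg] <- slope * x[neg]
  x
}

# Batched forward pass over a list of bit vectors.
# Returns final hidden state of the last layer (H x B), logits (K x B),
# probabilities (K x B), and (if cache = TRUE) all intermediates for BPTT.
gru_forward_batch <- function(params, cfg, seqs, cache = FALSE) {
  B <- length(seqs)
  lens <- lengths(seqs)
  Tm <- max(lens)
  H <- cfg$hidden_dim
  L <- cfg$n_layers
  ir <- seq_len(H); iz <- H + ir; ic <- 2L * H + ir
  X <- matrix(0, Tm, B)
  for (b in seq_len(B)) X[seq_len(lens[b]), b] <- seqs[[b]]
  mask <- matrix(0, Tm, B)
  for (b in seq_len(B)) mask[seq_len(lens[b]), b] <- 1
  caches <- if (cache) vector("list", L)
  Hout <- vector("list", L)  # per layer: list over t of H x B outputs
  for (l in seq_len(L)) {
    Wi <- params[[paste0("Wi", l)]]; Wh <- params[[paste0("Wh", l)]]
    bi <- params[[paste0("bi", l)]]; bh <- params[[paste0("bh", l)]]
    h <- matrix(0, H, B)
    outs <- vector("list", Tm)
    cc <- if (cache) vector("list", Tm)
    for (t in seq_len(Tm)) {
      x <- if (l == 1L) matrix(X[t, ], 1L, B) else Hout[[l - 1L]][[t]]
      gi <- Wi %*% x + bi
      gh <- Wh %*% h + bh
      r <- sigmoid(gi[ir, , drop = FALSE] + gh[ir, , drop = FALSE])
      z <- sigmoid(gi[iz, , drop = FALSE] + gh[iz, , drop = FALSE])
      hn <- gh[ic, , drop = FALSE]
      n <- tanh(gi[ic, , drop = FALSE] + r * hn)
      hc <- (1 - z) * n + z * h
      mm <- rep(mask[t, ], each = H)
      h_new <- hc * mm + h * (1 - mm)
      if (cache) cc[[t]] <- list(x = x, h_prev = h, r = r, z = z, n = n, hn = hn)
      h <- h_new
      outs[[t]] <- h
    }
    Hout[[l]] <- outs
    if (cache) caches[[l]] <- cc
  }
  hfin <- Hout[[L]][[Tm]]
  a <- leaky_relu(hfin, cfg$activation_negative_slope)
  logits <- params$V %*% a + params$cb
  probs <- apply(logits, 2L, softmax)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = cfg$n_species)
  out <- list(hfin = hfin, act = a, logits = logits, probs = probs,
              mask = mask, lens = lens)
  if (cache) {
    out$caches <- caches
    out$Hout <- Hout
  }
  out
}

# Mean cross-entropy of a forward result against integer labels (1..K).
gru_batch_loss <- function(fwd, labels) {
  B <- length(labels)
  p <- fwd$probs[cbind(labels, seq_len(B))]
  -mean(log(pmax(p, 1e-12)))
}

gru_loss <- function(params, cfg, seqs, labels) {
  gru_batch_loss(gru_forward_batch(params, cfg, seqs), labels)
}

# Full BPTT gradients of the mean cross-entropy over one batch.
gru_gradients <- function(params, cfg, seqs, labels) {
  fwd <- gru_forward_batch(params, cfg, seqs, cache = TRUE)
  B <- length(seqs)
  H <- cfg$hidden_dim
  L <- cfg$n_layers
  Tm <- max(fwd$lens)
  K <- cfg$n_species
  ir <- seq_len(H); iz <- H + ir; ic <- 2L * H + ir
  slope <- cfg$activation_negative_slope

  grads <- lapply(params, function(p) p * 0)

  Y <- matrix(0, K, B)
  Y[cbind(labels, seq_len(B))] <- 1
  dlogits <- (fwd$probs - Y) / B
  grads$V <- dlogits %*% t(fwd$act)
  grads$cb <- rowSums(dlogits)
  da <- t(params$V) %*% dlogits
  dleaky <- matrix(1, H, B)
  dleaky[fwd$hfin < 0] <- slope
  dh_top <- da * dleaky

  # dOut[[t]]: gradient wrt layer output at time t coming from above.
  dOut <- vector("list", Tm)
  for (t in seq_len(Tm)) dOut[[t]] <- matrix(0, H, B)
  dOut[[Tm]] <- dh_top

  for (l in rev(seq_len(L))) {
    Wi <- params[[paste0("Wi", l)]]; Wh <- params[[paste0("Wh", l)]]
    dWi <- grads[[paste0("Wi", l)]]; dWh <- grads[[paste0("Wh", l)]]
    dbi <- grads[[paste0("bi", l)]]; dbh <- grads[[paste0("bh", l)]]
    dX_lower <- if (l > 1L) vector("list", Tm)
    dh_rec <- matrix(0, H, B)
    for (t in rev(seq_len(Tm))) {
      cc <- fwd$caches[[l]][[t]]
      dh <- dOut[[t]] + dh_rec
      mm <- rep(fwd$mask[t, ], each = H)
      dhc <- dh * mm
      dh_prev <- dh * (1 - mm)
      dz <- dhc * (cc$h_prev - cc$n)
      dn <- dhc * (1 - cc$z)
      dh_prev <- dh_prev + dhc * cc$z
      dan <- dn * (1 - cc$n^2)
      dr <- dan * cc$hn
      dghn <- dan * cc$r
      dar <- dr * cc$r * (1 - cc$r)
      daz <- dz * cc$z * (1 - cc$z)
      dgi <- rbind(dar, daz, dan)
      dgh <- rbind(dar, daz, dghn)
      dWi <- dWi + dgi %*% t(cc$x)
      dbi <- dbi + rowSums(dgi)
      dWh <- dWh + dgh %*% t(cc$h_prev)
      dbh <- dbh + rowSums(dgh)
      if (l > 1L) dX_lower[[t]] <- t(Wi) %*% dgi
      dh_rec <- dh_prev + t(Wh) %*% dgh
    }
    grads[[paste0("Wi", l)]] <- dWi
    grads[[paste0("Wh", l)]] <- dWh
    grads[[paste0("bi", l)]] <- dbi
    grads[[paste0("bh", l)]] <- dbh
    if (l > 1L) dOut <- dX_lower
  }
  list(grads = grads, loss = gru_batch_loss(fwd, labels))
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
}

clip_gradients <- function(grads, max_norm) {
  gn <- grad_global_norm(grads)
  if (is.finite(gn) && gn > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / gn))
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
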