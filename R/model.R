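# Bidirectional LSTM next-residue model.
#
# The network maps a (window - 1)-residue integer context to a probability
# distribution over the 20 residues: stacked bidirectional LSTM layers (the
# forward and backward hidden states are concatenated at each position), the
# final states of the last layer feed ReLU dense layers and a softmax head.
# Implemented directly on base matrix algebra: forward pass here, exact
# backpropagation-through-time in train.R, verified against numerical
# gradients in the test suite.

#' Model hyperparameter configuration
#'
#' Defaults reproduce the reference architecture and schedule: a 35-residue
#' window (34-residue context), two stacked bidirectional LSTM layers of 256
#' units per direction, two ReLU dense layers, dropout 0.2 after each
#' recurrent layer, Adam at learning rate 1e-3, and a two-phase schedule of
#' 150 base epochs (batch 30) then 45 fine-tuning epochs (batch 62).
#'
#' @param window Sliding-window length in residues; the context is
#'   `window - 1` residues.
#' @param recurrent_layers Number of stacked bidirectional LSTM layers.
#' @param recurrent_units Hidden units per direction in each LSTM layer.
#' @param dense_layers Number of ReLU dense layers after the recurrent stack.
#' @param dense_units Units per dense layer.
#' @param dropout Dropout rate in `[0, 1)`, applied after each recurrent
#'   layer during training only.
#' @param vocab Vocabulary size (20 canonical residues).
#' @param learning_rate Adam step size.
#' @param clip_norm Global gradient-norm ceiling: per-batch gradients are
#'   rescaled when their overall L2 norm exceeds this value. The standard
#'   guard against the exploding-gradient spikes recurrent networks exhibit
#'   late in training; set `Inf` to disable.
#' @param epochs_base,epochs_finetune Epoch counts for the two phases.
#' @param batch_base,batch_finetune Minibatch sizes for the two phases.
#' @param rng_seed Integer seed governing weight initialisation, minibatch
#'   shuffling and dropout masks; the model's reproducibility contract.
#' @return A `pf_model_config` list.
#' @export
model_config <- function(window = 35L,
                         recurrent_layers = 2L,
                         recurrent_units = 256L,
                         dense_layers = 2L,
                         dense_units = 64L,
                         dropout = 0.2,
                         vocab = 20L,
                         learning_rate = 1e-3,
                         clip_norm = 5,
                         epochs_base = 150L,
                         epochs_finetune = 45L,
                         batch_base = 30L,
                         batch_finetune = 62L,
                         rng_seed = 42L) {
  cfg <- list(
    window = as.integer(window),
    recurrent_layers = as.integer(recurrent_layers),
    recurrent_units = as.integer(recurrent_units),
    dense_layers = as.integer(dense_layers),
    dense_units = as.integer(dense_units),
    dropout = as.numeric(dropout),
    vocab = as.integer(vocab),
    learning_rate = as.numeric(learning_rate),
    clip_norm = as.numeric(clip_norm),
    epochs_base = as.integer(epochs_base),
    epochs_finetune = as.integer(epochs_finetune),
    batch_base = as.integer(batch_base),
    batch_finetune = as.integer(batch_finetune),
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$window < 2L) stop2("`window` must be >= 2")
  for (f in c("recurrent_layers", "recurrent_units", "dense_units", "vocab",
              "batch_base", "batch_finetune")) {
    if (!is_positive_count(cfg[[f]])) stop2("`", f, "` must be a positive integer")
  }
  for (f in c("dense_layers", "epochs_base", "epochs_finetune")) {
    if (!is_count(cfg[[f]])) stop2("`", f, "` must be a non-negative integer")
  }
  if (is.na(cfg$dropout) || cfg$dropout < 0 || cfg$dropout >= 1) {
    stop2("`dropout` must lie in [0, 1)")
  }
  if (!is.finite(cfg$learning_rate) || cfg$learning_rate <= 0) {
    stop2("`learning_rate` must be positive")
  }
  if (is.na(cfg$clip_norm) || cfg$clip_norm <= 0) {
    stop2("`clip_norm` must be positive (use Inf to disable clipping)")
  }
  if (is.na(cfg$rng_seed)) stop2("`rng_seed` must be an integer")
  class(cfg) <- "pf_model_config"
  cfg
}

glorot_init <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nrow = nin, ncol = nout)
}

lstm_cell_init <- function(input_dim, units) {
  b <- numeric(4L * units)
  b[(units + 1L):(2L * units)] <- 1  # forget-gate bias at 1 aids early memory
  list(W = glorot_init(input_dim, 4L * units),
       R = glorot_init(units, 4L * units),
       b = b)
}

#' Build an untrained next-residue model
#'
#' Initialises all weights (Glorot-uniform, forget-gate biases at 1) under
#' the configuration seed, so identical configs yield identical models.
#'
#' @param config A [model_config()].
#' @return A `pf_model` with empty training history.
#' @export
build_model <- function(config) {
  if (!inherits(config, "pf_model_config")) stop2("`config` must come from model_config()")
  U <- config$recurrent_units
  params <- with_seed(config$rng_seed, {
    rec <- vector("list", config$recurrent_layers)
    din <- config$vocab
    for (l in seq_len(config$recurrent_layers)) {
      rec[[l]] <- list(fwd = lstm_cell_init(din, U), bwd = lstm_cell_init(din, U))
      din <- 2L * U
    }
    dense <- vector("list", config$dense_layers)
    for (l in seq_len(config$dense_layers)) {
      dense[[l]] <- list(W = glorot_init(din, config$dense_units),
                         b = numeric(config$dense_units))
      din <- config$dense_units
    }
    list(rec = rec, dense = dense,
         out = list(W = glorot_init(din, config$vocab), b = numeric(config$vocab)))
  })
  model <- list(
    config = config,
    params = params,
    history = data.frame(phase = character(0), epoch = integer(0),
                         loss = numeric(0), accuracy = numeric(0),
                         stringsAsFactors = FALSE),
    alphabet = paste(residue_alphabet(), collapse = "")
  )
  class(model) <- "pf_model"
  model
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# one-hot encode column t of a 0-based context matrix
one_hot_step <- function(codes, vocab) {
  M <- matrix(0, nrow = length(codes), ncol = vocab)
  M[cbind(seq_along(codes), codes + 1L)] <- 1
  M
}

# Run one LSTM direction over the full input sequence.
# X: list of T matrices (B x D). Returns hidden states per position and,
# optionally, the per-step activations needed for backpropagation.
lstm_dir_run <- function(X, cell, reverse = FALSE, keep_cache = FALSE) {
  Tlen <- length(X)
  B <- nrow(X[[1L]])
  U <- nrow(cell$R)
  ord <- if (reverse) rev(seq_len(Tlen)) else seq_len(Tlen)
  bmat <- matrix(cell$b, nrow = B, ncol = 4L * U, byrow = TRUE)
  h <- matrix(0, B, U)
  cs <- matrix(0, B, U)
  H <- vector("list", Tlen)
  cache <- if (keep_cache) vector("list", Tlen) else NULL
  i_idx <- seq_len(U); f_idx <- U + i_idx; g_idx <- 2L * U + i_idx; o_idx <- 3L * U + i_idx
  for (tt in ord) {
    Z <- X[[tt]] %*% cell$W + h %*% cell$R + bmat
    gi <- sigmoid(Z[, i_idx, drop = FALSE])
    gf <- sigmoid(Z[, f_idx, drop = FALSE])
    gg <- tanh(Z[, g_idx, drop = FALSE])
    go <- sigmoid(Z[, o_idx, drop = FALSE])
    cprev <- cs; hprev <- h
    cs <- gf * cprev + gi * gg
    tc <- tanh(cs)
    h <- go * tc
    H[[tt]] <- h
    if (keep_cache) {
      cache[[tt]] <- list(i = gi, f = gf, g = gg, o = go,
                          tc = tc, cprev = cprev, hprev = hprev)
    }
  }
  list(H = H, cache = cache, ord = ord)
}

# Full forward pass on a batch of contexts (B x (window-1), 0-based codes).
# With keep_cache = TRUE every intermediate needed by model_backward() is
# retained. Dropout masks are drawn from the current RNG stream when
# training = TRUE (inverted dropout; inference applies no mask).
model_forward <- function(model, ctx, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  Tlen <- cfg$window - 1L
  stopifnot(ncol(ctx) == Tlen)
  B <- nrow(ctx)
  U <- cfg$recurrent_units
  keep <- 1 - cfg$dropout
  X <- lapply(seq_len(Tlen), function(t) one_hot_step(ctx[, t], cfg$vocab))

  inputs <- vector("list", cfg$recurrent_layers)  # input sequence per layer
  runs <- vector("list", cfg$recurrent_layers)
  seq_masks <- vector("list", cfg$recurrent_layers)
  cur <- X
  for (l in seq_len(cfg$recurrent_layers)) {
    inputs[[l]] <- cur
    runf <- lstm_dir_run(cur, p$rec[[l]]$fwd, reverse = FALSE, keep_cache = keep_cache)
    runb <- lstm_dir_run(cur, p$rec[[l]]$bwd, reverse = TRUE, keep_cache = keep_cache)
    runs[[l]] <- list(fwd = runf, bwd = runb)
    if (l < cfg$recurrent_layers) {
      H <- lapply(seq_len(Tlen), function(t) cbind(runf$H[[t]], runb$H[[t]]))
      if (training && cfg$dropout > 0) {
        masks <- lapply(seq_len(Tlen), function(t) {
          matrix((stats::runif(B * 2L * U) >= cfg$dropout) / keep, B, 2L * U)
        })
        H <- lapply(seq_len(Tlen), function(t) H[[t]] * masks[[t]])
        seq_masks[[l]] <- masks
      }
      cur <- H
    }
  }
  last <- runs[[cfg$recurrent_layers]]
  feat <- cbind(last$fwd$H[[Tlen]], last$bwd$H[[1L]])  # final state, each direction
  feat_mask <- NULL
  if (training && cfg$dropout > 0) {
    feat_mask <- matrix((stats::runif(length(feat)) >= cfg$dropout) / keep,
                        nrow(feat), ncol(feat))
    feat <- feat * feat_mask
  }

  A <- feat
  dense_in <- vector("list", cfg$dense_layers)
  dense_z <- vector("list", cfg$dense_layers)
  for (l in seq_len(cfg$dense_layers)) {
    dense_in[[l]] <- A
    Z <- A %*% p$dense[[l]]$W +
      matrix(p$dense[[l]]$b, B, length(p$dense[[l]]$b), byrow = TRUE)
    dense_z[[l]] <- Z
    A <- pmax(Z, 0)
  }
  logits <- A %*% p$out$W + matrix(p$out$b, B, cfg$vocab, byrow = TRUE)
  e <- exp(logits - apply(logits, 1L, max))
  probs <- e / rowSums(e)

  out <- list(probs = probs)
  if (keep_cache) {
    out$X <- X; out$inputs <- inputs; out$runs <- runs
    out$seq_masks <- seq_masks; out$feat_mask <- feat_mask
    out$feat <- feat; out$dense_in <- dense_in; out$dense_z <- dense_z
    out$dense_out <- A
  }
  out
}

#' Probability distribution over the next residue
#'
#' Queries the model with a single integer context of length `window - 1`
#' and returns the softmax distribution over the 20 residues. Inference is
#' deterministic (dropout disabled).
#'
#' @param model A `pf_model`.
#' @param context Integer vector of length `window - 1` with values in
#'   `0:19`.
#' @return Named numeric vector of 20 probabilities summing to 1.
#' @export
next_distribution <- function(model, context) {
  stopifnot(inherits(model, "pf_model"))
  context <- as.integer(context)
  Tlen <- model$config$window - 1L
  if (length(context) != Tlen) {
    stop2(sprintf("context must have exactly %d residues, got %d",
                  Tlen, length(context)))
  }
  if (anyNA(context) || any(context < 0L | context >= model$config$vocab)) {
    stop2("context codes must lie in 0..", model$config$vocab - 1L)
  }
  pr <- model_forward(model, matrix(context, nrow = 1L))$probs
  stats::setNames(drop(pr), residue_alphabet())
}

#' Retrieve the per-epoch training history
#'
#' @param model A `pf_model`.
#' @return Data frame with columns `phase`, `epoch`, `loss` (mean categorical
#'   cross-entropy per window, nats) and `accuracy` (fraction of windows
#'   whose argmax prediction equals the target).
#' @export
training_history <- function(model) {
  stopifnot(inherits(model, "pf_model"))
  model$history
}

#' @export
print.pf_model <- function(x, ...) {
  cfg <- x$config
  np <- length(unlist(x$params, use.names = FALSE))
  cat(sprintf(
    "<pf_model> BiLSTM next-residue model: %d-residue context, %d x %d units/dir, %d params\n",
    cfg$window - 1L, cfg$recurrent_layers, cfg$recurrent_units, np))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  trained: %s (last: %s epoch %d, loss %.4f, acc %.3f)\n",
                paste(unique(x$history$phase), collapse = " -> "),
                last$phase, last$epoch, last$loss, last$accuracy))
  } else {
    cat("  untrained\n")
  }
  invisible(x)
}
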