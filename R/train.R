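# Backpropagation-through-time and the two-phase training loop.
#
# Gradients are computed analytically for every parameter; correctness is
# pinned down by a central-difference numerical-gradient test. Adam runs on
# the flattened parameter vector (unlist/relist keeps the nested shape and
# the flat optimizer state in exact correspondence).

# Backward pass through one LSTM direction.
# dHext: list of external gradients w.r.t. the hidden state at each position
# (NULL entries mean zero). Returns parameter gradients and the gradient
# w.r.t. the layer input sequence.
lstm_dir_backward <- function(X, cell, run, dHext) {
  Tlen <- length(X)
  B <- nrow(X[[1L]])
  U <- nrow(cell$R)
  dW <- matrix(0, nrow(cell$W), ncol(cell$W))
  dR <- matrix(0, U, 4L * U)
  db <- numeric(4L * U)
  dh <- matrix(0, B, U)
  dc <- matrix(0, B, U)
  dX <- vector("list", Tlen)
  for (tt in rev(run$ord)) {
    s <- run$cache[[tt]]
    dh_t <- dh
    if (!is.null(dHext[[tt]])) dh_t <- dh_t + dHext[[tt]]
    dc_t <- dc + dh_t * s$o * (1 - s$tc^2)
    dzo <- (dh_t * s$tc) * s$o * (1 - s$o)
    dzi <- (dc_t * s$g) * s$i * (1 - s$i)
    dzg <- (dc_t * s$i) * (1 - s$g^2)
    dzf <- (dc_t * s$cprev) * s$f * (1 - s$f)
    dZ <- cbind(dzi, dzf, dzg, dzo)
    dW <- dW + crossprod(X[[tt]], dZ)
    dR <- dR + crossprod(s$hprev, dZ)
    db <- db + colSums(dZ)
    dX[[tt]] <- tcrossprod(dZ, cell$W)
    dh <- tcrossprod(dZ, cell$R)
    dc <- dc_t * s$f
  }
  list(W = dW, R = dR, b = db, dX = dX)
}

# Full backward pass. fw is a model_forward(..., keep_cache = TRUE) result,
# target is the 0-based target code per batch row. Returns gradients with
# exactly the same nesting as model$params (so unlist() orders match).
model_backward <- function(model, fw, target) {
  cfg <- model$config
  p <- model$params
  B <- nrow(fw$probs)
  U <- cfg$recurrent_units
  Tlen <- cfg$window - 1L

  Y <- matrix(0, B, cfg$vocab)
  Y[cbind(seq_len(B), target + 1L)] <- 1
  dlogits <- (fw$probs - Y) / B

  g_out <- list(W = crossprod(fw$dense_out, dlogits), b = colSums(dlogits))
  dA <- tcrossprod(dlogits, p$out$W)
  g_dense <- vector("list", cfg$dense_layers)
  for (l in rev(seq_len(cfg$dense_layers))) {
    dZ <- dA * (fw$dense_z[[l]] > 0)
    g_dense[[l]] <- list(W = crossprod(fw$dense_in[[l]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, p$dense[[l]]$W)
  }
  dfeat <- dA
  if (!is.null(fw$feat_mask)) dfeat <- dfeat * fw$feat_mask

  g_rec <- vector("list", cfg$recurrent_layers)
  # top layer: gradient arrives only at each direction's final state
  dHf <- vector("list", Tlen)
  dHb <- vector("list", Tlen)
  dHf[[Tlen]] <- dfeat[, seq_len(U), drop = FALSE]
  dHb[[1L]] <- dfeat[, U + seq_len(U), drop = FALSE]

  for (l in rev(seq_len(cfg$recurrent_layers))) {
    bf <- lstm_dir_backward(fw$inputs[[l]], p$rec[[l]]$fwd, fw$runs[[l]]$fwd, dHf)
    bb <- lstm_dir_backward(fw$inputs[[l]], p$rec[[l]]$bwd, fw$runs[[l]]$bwd, dHb)
    g_rec[[l]] <- list(fwd = bf[c("W", "R", "b")], bwd = bb[c("W", "R", "b")])
    if (l > 1L) {
      dIn <- lapply(seq_len(Tlen), function(t) bf$dX[[t]] + bb$dX[[t]])
      if (!is.null(fw$seq_masks[[l - 1L]])) {
        dIn <- lapply(seq_len(Tlen), function(t) dIn[[t]] * fw$seq_masks[[l - 1L]][[t]])
      }
      dHf <- lapply(dIn, function(m) m[, seq_len(U), drop = FALSE])
      dHb <- lapply(dIn, function(m) m[, U + seq_len(U), drop = FALSE])
    }
  }
  list(rec = g_rec, dense = g_dense, out = g_out)
}

batch_loss <- function(probs, target) {
  pt <- probs[cbind(seq_len(nrow(probs)), target + 1L)]
  -mean(log(pmax(pt, 1e-12)))
}

#' Train the model for one phase
#'
#' Runs minibatch Adam on categorical cross-entropy over the supplied
#' training windows. The two phases differ only in which epoch/batch-size
#' pair they take from the configuration: `"base"` uses
#' `epochs_base`/`batch_base`, `"finetune"` uses
#' `epochs_finetune`/`batch_finetune`. Fine-tuning continues from the
#' parameters the model currently holds, so the usual call sequence is
#' base phase first, then fine-tune. All stochastic elements (shuffling,
#' dropout) are driven by the configuration seed plus a fixed per-phase
#' offset, making training reproducible.
#'
#' @param model A `pf_model`.
#' @param windows A `pf_windows` training set whose context width matches
#'   the model window.
#' @param phase `"base"` or `"finetune"`.
#' @param epochs,batch_size Optional overrides of the configured schedule.
#' @return The model with updated parameters and per-epoch history rows
#'   appended (see [training_history()]). `epochs = 0` returns the model
#'   unchanged.
#' @export
train_phase <- function(model, windows, phase = c("base", "finetune"),
                        epochs = NULL, batch_size = NULL) {
  stopifnot(inherits(model, "pf_model"), inherits(windows, "pf_windows"))
  phase <- match.arg(phase)
  cfg <- model$config
  N <- length(windows$target)
  if (N == 0L) stop2("training-window set is empty")
  if (ncol(windows$context) != cfg$window - 1L) {
    stop2(sprintf("window context width %d does not match model window %d",
                  ncol(windows$context) + 1L, cfg$window))
  }
  if (is.null(epochs)) {
    epochs <- if (phase == "base") cfg$epochs_base else cfg$epochs_finetune
  }
  if (is.null(batch_size)) {
    batch_size <- if (phase == "base") cfg$batch_base else cfg$batch_finetune
  }
  epochs <- as.integer(epochs)
  batch_size <- as.integer(batch_size)
  if (!is_count(epochs)) stop2("`epochs` must be a non-negative integer")
  if (!is_positive_count(batch_size)) stop2("`batch_size` must be positive")
  if (epochs == 0L) return(model)

  lr <- cfg$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  pvec <- unlist(model$params, use.names = FALSE)
  m <- numeric(length(pvec))
  v <- numeric(length(pvec))
  tstep <- 0L
  hist_rows <- vector("list", epochs)
  phase_seed <- cfg$rng_seed + if (phase == "base") 1L else 2L

  with_seed(phase_seed, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(N)
      starts <- seq(1L, N, by = batch_size)
      ep_loss <- 0; ep_correct <- 0L
      for (st in starts) {
        idx <- perm[st:min(st + batch_size - 1L, N)]
        ctx <- windows$context[idx, , drop = FALSE]
        y <- windows$target[idx]
        fw <- model_forward(model, ctx, training = TRUE, keep_cache = TRUE)
        ep_loss <- ep_loss + batch_loss(fw$probs, y) * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(fw$probs, ties.method = "first") - 1L == y)
        grads <- model_backward(model, fw, y)
        gvec <- unlist(grads, use.names = FALSE)
        gnorm <- sqrt(sum(gvec * gvec))
        if (is.finite(cfg$clip_norm) && gnorm > cfg$clip_norm) {
          gvec <- gvec * (cfg$clip_norm / gnorm)
        }
        tstep <- tstep + 1L
        m <- beta1 * m + (1 - beta1) * gvec
        v <- beta2 * v + (1 - beta2) * gvec * gvec
        mhat <- m / (1 - beta1^tstep)
        vhat <- v / (1 - beta2^tstep)
        pvec <- pvec - lr * mhat / (sqrt(vhat) + eps)
        model$params <- utils::relist(pvec, model$params)
      }
      hist_rows[[ep]] <- data.frame(
        phase = phase, epoch = ep, loss = ep_loss / N,
        accuracy = ep_correct / N, stringsAsFactors = FALSE
      )
    }
  })
  model$history <- rbind(model$history, do.call(rbind, hist_rows))
  model
}

#' Evaluate loss and accuracy on a window set
#'
#' Deterministic (dropout-free) forward pass over all windows; useful for
#' measuring final fit independently of the running training averages.
#'
#' @inheritParams train_phase
#' @param batch_size Evaluation chunk size (memory only, no effect on
#'   results).
#' @return List with `loss` (mean cross-entropy, nats) and `accuracy`.
#' @export
evaluate_windows <- function(model, windows, batch_size = 256L) {
  stopifnot(inherits(model, "pf_model"), inherits(windows, "pf_windows"))
  N <- length(windows$target)
  if (N == 0L) stop2("window set is empty")
  tot_loss <- 0; correct <- 0L
  for (st in seq(1L, N, by = batch_size)) {
    idx <- st:min(st + batch_size - 1L, N)
    fw <- model_forward(model, windows$context[idx, , drop = FALSE])
    tot_loss <- tot_loss + batch_loss(fw$probs, windows$target[idx]) * length(idx)
    correct <- correct +
      sum(max.col(fw$probs, ties.method = "first") - 1L == windows$target[idx])
  }
  list(loss = tot_loss / N, accuracy = correct / N)
}
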