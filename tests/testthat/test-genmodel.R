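tiny_config <- function(...) {
  model_config(window = 6L, recurrent_layers = 2L, recurrent_units = 5L,
               dense_layers = 2L, dense_units = 7L, dropout = 0,
               rng_seed = 7L, ...)
}

test_that("model_config validates its fields", {
  expect_s3_class(model_config(), "pf_model_config")
  expect_error(model_config(window = 1), "window")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(dropout = -0.1), "dropout")
  expect_error(model_config(recurrent_units = 0), "recurrent_units")
  expect_error(model_config(learning_rate = 0), "learning_rate")
  expect_error(build_model(list()), "model_config")
})

test_that("untrained model emits a valid, deterministic distribution and enforces the contract", {
  m <- build_model(tiny_config())
  ctx <- sample(0:19, 5, replace = TRUE)
  p <- next_distribution(m, ctx)
  expect_length(p, 20L)
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_identical(p, next_distribution(m, ctx))  # inference determinism

  expect_error(next_distribution(m, ctx[-1]), "exactly 5")
  expect_error(next_distribution(m, c(ctx[-1], 20L)), "0..19")

  # identical config and seed -> identical weights
  m2 <- build_model(tiny_config())
  expect_identical(m$params, m2$params)
})

test_that("analytic gradients match central differences", {
  m <- build_model(tiny_config())
  set.seed(99)
  ctx <- matrix(sample(0:19, 4 * 5, replace = TRUE), 4, 5)
  y <- sample(0:19, 4, replace = TRUE)
  fw <- pepfunnel:::model_forward(m, ctx, training = TRUE, keep_cache = TRUE)
  g <- unlist(pepfunnel:::model_backward(m, fw, y), use.names = FALSE)
  pv <- unlist(m$params, use.names = FALSE)
  lossfun <- function(p) {
    m$params <- utils::relist(p, m$params)
    pepfunnel:::batch_loss(pepfunnel:::model_forward(m, ctx)$probs, y)
  }
  idx <- sample(length(pv), 50)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    up <- pv; up[i] <- up[i] + eps
    dn <- pv; dn[i] <- dn[i] - eps
    (lossfun(up) - lossfun(dn)) / (2 * eps)
  }, numeric(1))
  expect_equal(g[idx], num, tolerance = 1e-5)
})

test_that("training reduces loss and memorises a deterministic successor map", {
  fx <- successor_fixture()
  h <- training_history(fx$model)
  expect_identical(nrow(h), 80L)
  expect_true(all(h$loss >= 0))
  expect_true(all(h$accuracy >= 0 & h$accuracy <= 1))
  expect_lt(h$loss[nrow(h)], h$loss[1])

  ev <- evaluate_windows(fx$model, fx$windows)
  expect_gte(ev$accuracy, 0.98)

  # argmax prediction equals the planted successor on >= 95% of contexts
  succ <- fx$corpus$successor
  ctx <- fx$windows$context
  take <- seq_len(min(100L, nrow(ctx)))
  hits <- vapply(take, function(i) {
    last_res <- residue_alphabet()[ctx[i, ncol(ctx)] + 1L]
    pred <- names(which.max(next_distribution(fx$model, ctx[i, ])))
    identical(pred, unname(succ[last_res]))
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("zero epochs is a no-op and empty windows are rejected", {
  m <- build_model(tiny_config())
  w <- make_windows(sample(0:19, 20, replace = TRUE), window = 6L)
  m0 <- train_phase(m, w, "base", epochs = 0L)
  expect_identical(m0$params, m$params)
  expect_identical(nrow(training_history(m0)), 0L)

  empty <- suppressWarnings(make_windows(sample(0:19, 3), window = 6L))
  expect_error(train_phase(m, empty, "base"), "empty")
})

test_that("training is reproducible and fine-tuning continues from base parameters", {
  corpus <- deterministic_successor_corpus(rng_seed = 5L, n = 3L, length = 60L)
  w <- corpus_windows(corpus$records)
  cfg <- model_config(recurrent_units = 8L, dense_units = 16L, dropout = 0.2,
                      epochs_base = 3L, batch_base = 16L,
                      epochs_finetune = 2L, batch_finetune = 16L, rng_seed = 13L)
  run <- function() {
    m <- train_phase(build_model(cfg), w, "base")
    train_phase(m, w, "finetune")
  }
  m1 <- run(); m2 <- run()
  expect_identical(training_history(m1), training_history(m2))
  expect_identical(m1$params, m2$params)
  expect_identical(unique(training_history(m1)$phase), c("base", "finetune"))
  # fine-tuning changed the parameters but preserved output validity
  mb <- train_phase(build_model(cfg), w, "base")
  expect_false(identical(mb$params, m1$params))
  p <- next_distribution(m1, w$context[1, ])
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("loss on a uniform-random corpus sits near log(20) nats", {
  set.seed(3)
  recs <- protein_records(
    sprintf("U%02d", 1:5),
    replicate(5, paste(sample(residue_alphabet(), 80, TRUE), collapse = ""))
  )
  w <- corpus_windows(recs)
  cfg <- model_config(recurrent_units = 8L, dense_units = 16L, dropout = 0,
                      epochs_base = 15L, batch_base = 32L, rng_seed = 3L)
  m <- train_phase(build_model(cfg), w, "base")
  ev <- evaluate_windows(m, w)
  expect_equal(ev$loss, log(20), tolerance = 0.1)
})

test_that("checkpoints round-trip models and reject corrupt files", {
  f <- tempfile(fileext = ".ckpt")
  m <- build_model(tiny_config())
  ctx <- sample(0:19, 5, replace = TRUE)
  save_checkpoint(m, f)
  back <- load_checkpoint(f)
  expect_identical(unclass(back$config), unclass(m$config))
  expect_equal(next_distribution(back, ctx), next_distribution(m, ctx),
               tolerance = 1e-6)

  # trained model round trip
  fx <- successor_fixture()
  save_checkpoint(fx$model, f)
  tb <- load_checkpoint(f)
  c2 <- fx$windows$context[3, ]
  expect_equal(next_distribution(tb, c2), next_distribution(fx$model, c2),
               tolerance = 1e-6)
  expect_identical(training_history(tb), training_history(fx$model))

  # truncated file -> error, no partial model
  raw_all <- readBin(f, "raw", file.info(f)$size)
  writeBin(raw_all[seq_len(200)], f)
  expect_error(load_checkpoint(f), "checkpoint")
  saveRDS(list(a = 1), f)
  expect_error(load_checkpoint(f), "not a pepfunnel checkpoint")
  expect_error(load_checkpoint(tempfile()), "not found")
})
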