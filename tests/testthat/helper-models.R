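# Small trained models shared across test files, built once per run.
.pf_test_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, builder) {
  if (!exists(key, envir = .pf_test_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .pf_test_cache)
  }
  get(key, envir = .pf_test_cache, inherits = FALSE)
}

# model trained to convergence on the deterministic-successor corpus
successor_fixture <- function() {
  memoise_fixture("successor", function() {
    corpus <- deterministic_successor_corpus(rng_seed = 11L, n = 6L, length = 120L)
    windows <- corpus_windows(corpus$records)
    cfg <- model_config(recurrent_units = 24L, dense_units = 32L,
                        dropout = 0.2, epochs_base = 80L, batch_base = 32L,
                        rng_seed = 11L)
    model <- train_phase(build_model(cfg), windows, "base")
    list(corpus = corpus, windows = windows, model = model)
  })
}

# full-shape study: default motif corpus (7 base proteins, 6 fine-tune
# peptides), a compact model trained in both phases, and the default
# 1,000-peptide pool. Built once and shared by the acceptance tests.
study_fixture <- function() {
  memoise_fixture("study", function() {
    corpus <- motif_corpus(motif_corpus_spec(rng_seed = 101L))
    all_records <- rbind(corpus$base, corpus$finetune)
    class(all_records) <- c("pf_records", "data.frame")
    cfg <- model_config(recurrent_units = 32L, dense_units = 32L,
                        epochs_base = 8L, epochs_finetune = 4L,
                        rng_seed = 101L)
    model <- build_model(cfg)
    model <- train_phase(model, corpus_windows(corpus$base), "base")
    model <- train_phase(model, corpus_windows(corpus$finetune), "finetune")
    pool <- generate_pool(model, all_records,
                          generation_config(rng_seed = 101L))
    list(corpus = corpus, records = all_records, model = model, pool = pool)
  })
}

# small model briefly trained on a compact motif corpus, for generator tests
motif_fixture <- function() {
  memoise_fixture("motif", function() {
    spec <- motif_corpus_spec(n_base = 4L, base_len_range = c(150L, 250L),
                              motif_rate = 8, rng_seed = 21L)
    corpus <- motif_corpus(spec)
    all_records <- rbind(corpus$base, corpus$finetune)
    class(all_records) <- c("pf_records", "data.frame")
    wb <- corpus_windows(corpus$base)
    cfg <- model_config(recurrent_units = 16L, dense_units = 32L,
                        dropout = 0.1, epochs_base = 6L, batch_base = 32L,
                        rng_seed = 21L)
    model <- train_phase(build_model(cfg), wb, "base")
    list(spec = spec, corpus = corpus, records = all_records, model = model)
  })
}
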